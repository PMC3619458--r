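# Independent brute-force oracles and small fixtures, kept deliberately
# naive (explicit loops, no shared code with the package internals).

# entropy / mutual information / VI from two label vectors over their
# common names, via an explicitly built contingency table
info_oracle <- function(labels_a, labels_b) {
  common <- intersect(names(labels_a), names(labels_b))
  a <- labels_a[common]
  b <- labels_b[common]
  n <- length(common)
  ta <- unique(a)
  tb <- unique(b)
  joint <- matrix(0, length(ta), length(tb), dimnames = list(ta, tb))
  for (id in common) joint[a[[id]], b[[id]]] <- joint[a[[id]], b[[id]]] + 1
  pa <- rowSums(joint) / n
  pb <- colSums(joint) / n
  ha <- 0
  for (p in pa) if (p > 0) ha <- ha - p * log(p)
  hb <- 0
  for (p in pb) if (p > 0) hb <- hb - p * log(p)
  mi <- 0
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      pij <- joint[i, j] / n
      if (pij > 0) mi <- mi + pij * log(pij / (pa[i] * pb[j]))
    }
  }
  list(ha = unname(ha), hb = unname(hb), mi = unname(mi),
       vi = unname(ha + hb - 2 * mi))
}

# exact mutation matrix by explicit recursion over every data sequence
q_oracle <- function(space, data_size) {
  H <- nrow(space$hypotheses)
  n <- space$n_sites
  eps <- space$eps
  lik1 <- function(site, y, h) {
    (1 / n) * if (space$hypotheses[h, site] == y) 1 - eps else eps
  }
  seq_lik <- function(d, h) {
    out <- 1
    for (obs in d) out <- out * lik1(obs[1], obs[2], h)
    out
  }
  outcomes <- list()
  for (s in seq_len(n)) for (y in 0:1) outcomes[[length(outcomes) + 1]] <- c(s, y)
  idx <- expand.grid(rep(list(seq_along(outcomes)), data_size))
  Q <- matrix(0, H, H)
  for (r in seq_len(nrow(idx))) {
    d <- lapply(as.integer(idx[r, ]), function(i) outcomes[[i]])
    lik <- vapply(seq_len(H), function(h) seq_lik(d, h), numeric(1))
    post <- lik * space$prior
    if (sum(post) > 0) post <- post / sum(post) else post <- rep(0, H)
    for (j in seq_len(H)) Q[, j] <- Q[, j] + post * lik[j]
  }
  Q
}

# deterministic nearest-exemplar labelling (independent of the package's
# softmax path); ties resolved to the lexicographically first term
nearest_term_oracle <- function(examples, grid, rho = 3, warp = 0) {
  emb <- perceptual_embedding(grid, rho = rho, warp = warp)
  ex_emb <- emb[examples$chip_id, , drop = FALSE]
  out <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- sqrt(rowSums((ex_emb - matrix(emb[i, ], nrow(ex_emb), 3,
                                       byrow = TRUE))^2))
    cand <- sort(unique(examples$term[d <= min(d) + 1e-12]))
    out[i] <- cand[1]
  }
  stats::setNames(out, grid$chip_id)
}

# tiny corpus with hand-chosen systems over a shared grid
make_tiny_corpus <- function(grid, k = 3, n_lang = 3, n_spk = 2, seed = 99) {
  langs <- list()
  for (l in seq_len(n_lang)) {
    spk <- list()
    for (s in seq_len(n_spk)) {
      spk[[paste0("s", s)]] <- random_partition(grid, k, seed = seed + 10 * l + s)
    }
    langs[[paste0("lang", l)]] <- spk
  }
  speaker_corpus(langs)
}
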