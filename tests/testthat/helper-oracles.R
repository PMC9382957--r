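# Independent oracles and small constructors used across tests.

# average ranks computed by counting, independent of base rank()
rank_avg <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

pearson_oracle <- function(a, b) {
  ac <- a - mean(a); bc <- b - mean(b)
  den <- sqrt(sum(ac^2) * sum(bc^2))
  if (den == 0) return(NA_real_)
  sum(ac * bc) / den
}

spearman_oracle <- function(x, y) {
  pearson_oracle(rank_avg(x), rank_avg(y))
}

# wrap a bare counts matrix as a production_matrix
toy_pm <- function(counts, group = "toy") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("w", seq_len(ncol(counts)))
  structure(list(age_group = group,
                 vignette_ids = seq_len(nrow(counts)),
                 words = colnames(counts), counts = counts),
            class = "production_matrix")
}

# brute-force co-naming counts by enumerating participants x pairs
similarity_oracle <- function(coded, group, vignette_ids) {
  nv <- length(vignette_ids)
  s <- matrix(0L, nv, nv)
  npair <- matrix(0L, nv, nv)
  d <- coded[coded$age_group == group, ]
  uncodable <- c("not_emotion", "no_answer")
  for (pid in unique(d$participant_id)) {
    p <- d[d$participant_id == pid, ]
    for (i in seq_len(nv)) for (j in seq_len(nv)) {
      ci <- p$code[p$vignette_id == vignette_ids[i]]
      cj <- p$code[p$vignette_id == vignette_ids[j]]
      if (length(ci) == 1 && length(cj) == 1 &&
          !ci %in% uncodable && !cj %in% uncodable) {
        npair[i, j] <- npair[i, j] + 1L
        if (ci == cj) s[i, j] <- s[i, j] + 1L
      }
    }
  }
  list(s = s, n_pairs = npair)
}

# per-point silhouette of a two-group split along one coordinate
silhouette_1d <- function(x, grp) {
  vapply(seq_along(x), function(i) {
    same <- which(grp == grp[i])[which(grp == grp[i]) != i]
    other <- which(grp != grp[i])
    a <- if (length(same)) mean(abs(x[i] - x[same])) else 0
    b <- mean(abs(x[i] - x[other]))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

noise_free_params <- function(seed = 1, ...) {
  simulation_params(
    dont_know_rate = c("4-5" = 0, "6-7" = 0, "8-9" = 0,
                       "10-11" = 0, "adult" = 0),
    valence_error_rate = 0, seed = seed, ...)
}

# small coded data.frame from a participant x vignette code matrix
coded_from_matrix <- function(codes, group = "g") {
  n <- nrow(codes); nv <- ncol(codes)
  data.frame(
    participant_id = rep(sprintf("p%02d", seq_len(n)), each = nv),
    age_group = group,
    vignette_id = rep(seq_len(nv), times = n),
    answer = as.vector(t(codes)),
    code = as.vector(t(codes)),
    stringsAsFactors = FALSE)
}
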