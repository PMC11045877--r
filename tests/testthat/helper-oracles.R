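# Brute-force reference implementations, written independently of the
# package internals: plain loops and queue-based flood fill.

# per-pixel loop maximum over z, one channel; preserves storage type
oracle_projection <- function(arr) {
  d <- dim(arr)
  out <- arr[, , 1L]
  dim(out) <- d[1:2]
  for (i in seq_len(d[1L]))
    for (j in seq_len(d[2L]))
      for (z in seq_len(d[3L]))
        if (arr[i, j, z] > out[i, j]) out[i, j] <- arr[i, j, z]
  out
}

# loop mean under a mask
oracle_mask_mean <- function(plane, mask) {
  s <- 0; n <- 0L
  for (i in seq_len(nrow(plane)))
    for (j in seq_len(ncol(plane)))
      if (mask[i, j]) {
        s <- s + plane[i, j]
        n <- n + 1L
      }
  s / n
}

# flood-fill connected-component labeling; connectivity 4 or 8
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (!mask[si, sj] || lab[si, sj] > 0L) next
    cur <- cur + 1L
    queue <- list(c(si, sj))
    lab[si, sj] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(nbr))) {
        ii <- p[1L] + nbr[k, 1L]; jj <- p[2L] + nbr[k, 2L]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# exhaustive spot selection: label, filter by area, rank by mean marker
# (desc), tie-break larger area; return list of sorted pixel index vectors
oracle_spot_select <- function(marker, nucleus_mask, spot_thr,
                               min_area, max_spots) {
  cand <- (marker >= spot_thr) & nucleus_mask
  lab <- oracle_label(cand, 8L)
  comps <- list()
  if (max(lab) > 0L)
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k)
      if (length(idx) >= min_area)
        comps[[length(comps) + 1L]] <-
          list(idx = idx, area = length(idx), mm = mean(marker[idx]))
    }
  if (!length(comps)) return(list())
  ord <- order(-vapply(comps, `[[`, 0, "mm"),
               -vapply(comps, `[[`, 0, "area"))
  comps <- comps[ord[seq_len(min(max_spots, length(comps)))]]
  lapply(comps, function(co) sort(co$idx))
}

# two-sided permutation test for a difference in means
oracle_permutation_p <- function(a, b, n_perm = 1e5L, seed = 1L) {
  set.seed(seed)
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0L
  total <- sum(pooled)
  for (k in seq_len(n_perm)) {
    ia <- sample.int(length(pooled), na)
    da <- mean(pooled[ia])
    db <- (total - sum(pooled[ia])) / (length(pooled) - na)
    if (abs(da - db) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1L) / (n_perm + 1L)
}

# closed-form one-way ANOVA F from between/within mean squares
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  k <- length(groups)
  n <- length(all_v)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - gm)^2, 0))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), 0))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}
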