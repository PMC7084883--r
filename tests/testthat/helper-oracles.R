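# Independent O(n^2) oracles and fixture builders.  These deliberately use
# only base R (dist / full distance matrices) so they share no code path
# with the grid-based neighbour search they check.

oracle_pairs_within <- function(pts, r) {
  n <- nrow(pts)
  if (n < 2) return(matrix(integer(), 0, 2))
  d <- as.matrix(dist(pts))
  idx <- which(upper.tri(d) & d <= r, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

oracle_n_within <- function(pts, centers, r) {
  vapply(seq_len(nrow(centers)), function(k) {
    dd <- sqrt((pts[, 1] - centers[k, 1])^2 + (pts[, 2] - centers[k, 2])^2 +
               (pts[, 3] - centers[k, 3])^2)
    sum(dd <= r)
  }, integer(1))
}

make_event_set <- function(pts, edep = 20, kind = "ION", track = 1L) {
  n <- nrow(pts)
  EventSet(data.frame(track_id = rep_len(track, n), x_nm = pts[, 1],
                      y_nm = pts[, 2], z_nm = pts[, 3],
                      kind = rep_len(kind, n),
                      edep_eV = rep_len(edep, n)))
}

random_event_set <- function(n, boxNm = 20, seed = 1) {
  set.seed(seed)
  make_event_set(matrix(runif(3 * n, -boxNm, boxNm), ncol = 3),
                 edep = runif(n, 1, 50),
                 kind = sample(c("ION", "EXC"), n, replace = TRUE))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}
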