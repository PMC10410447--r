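# Small in-code fixtures shared across test files.

rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rand_rigid <- function(coords) {
  R <- rand_rotation()
  t <- rnorm(3, sd = 5)
  sweep(coords %*% R, 2, t, "+")
}

# a random anchored loop with a well-spread (non-degenerate) anchor set
rand_anchored_loop <- function(L, id = NULL, loop_sd = 2) {
  anc <- cbind(c(seq(-10, -2, length.out = 5), seq(2, 10, length.out = 5)),
               rep(c(-1, 1), 10), rep(c(0.5, -0.5, 0.2, -0.2), 10))
  anc <- anc[rep(1:10, each = 4), ] + matrix(rnorm(120, sd = 0.3), 40)
  loop <- matrix(rnorm(L * 4 * 3, sd = loop_sd), L * 4, 3)
  loop[, 3] <- loop[, 3] + 5
  anchored_loop(loop, anc, id = id)
}

# move loop and anchors rigidly together
move_anchored_loop <- function(al) {
  R <- rand_rotation(); t <- rnorm(3, sd = 8)
  anchored_loop(sweep(al$loop_bb %*% R, 2, t, "+"),
                sweep(al$anchor_bb %*% R, 2, t, "+"), id = al$id)
}

# match cluster labels to truth by best permutation, return agreement rate
label_agreement <- function(labels, truth) {
  labs <- sort(unique(labels))
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- 0
  for (p in perms(labs)) {
    mapped <- p[match(labels, labs)]
    best <- max(best, mean(mapped == truth))
  }
  best
}
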