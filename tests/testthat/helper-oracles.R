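# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately re-derive each quantity by brute force or from the
# textbook formula, without calling the package code paths they check.

# brute-force segment-plane intersection count: walks every edge of every
# tree and tests the x-interval directly
oracle_crossings <- function(trees, distance, crush_x = 0) {
  total <- 0L
  for (tree in trees) {
    for (row in seq_len(nrow(tree))) {
      p <- tree$parent[row]
      if (p == -1L) next
      x1 <- tree$x[match(p, tree$id)] - crush_x
      x2 <- tree$x[row] - crush_x
      lo <- min(x1, x2)
      hi <- max(x1, x2)
      # half-open: crossing when the plane lies in [lo, hi) on one side
      if ((x1 < distance && x2 >= distance) ||
          (x2 < distance && x1 >= distance)) {
        total <- total + 1L
      }
    }
  }
  total
}

# textbook pooled-variance two-sample t
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# textbook one-sample t
oracle_one_t <- function(x, mu) {
  tt <- (mean(x) - mu) / (stats::sd(x) / sqrt(length(x)))
  df <- length(x) - 1
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# textbook one-way ANOVA F and Tukey HSD adjusted p (studentized range)
oracle_anova <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  mse <- ssw / df2
  pairs <- utils::combn(k, 2)
  tukey <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    ni <- length(groups[[i]]); nj <- length(groups[[j]])
    diff <- mean(groups[[j]]) - mean(groups[[i]])
    se <- sqrt(mse / 2 * (1 / ni + 1 / nj))
    q <- abs(diff) / se
    c(diff = diff, p_adj = stats::ptukey(q, k, df2, lower.tail = FALSE))
  })
  list(f = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2,
                                                  lower.tail = FALSE),
       tukey = t(tukey))
}

# straight axon along +x of given length, rooted at the crush plane
make_straight_tree <- function(length_um, step = 10, y = 0, z = 0,
                               radius = 1) {
  xs <- seq(0, length_um, by = step)
  if (xs[length(xs)] != length_um) xs <- c(xs, length_um)
  axon_tree(data.frame(id = seq_along(xs),
                       parent = c(-1L, seq_along(xs)[-length(xs)]),
                       x = xs, y = y, z = z, radius = radius))
}

# unbranched tree that doubles back along -x at its end
make_uturn_tree <- function(out_len = 200, back_len = 60, y = 0) {
  xs_out <- seq(0, out_len, by = 10)
  xs_back <- seq(out_len - 10, out_len - back_len, by = -10)
  xs <- c(xs_out, xs_back)
  ys <- c(rep(y, length(xs_out)), rep(y + 8, length(xs_back)))
  axon_tree(data.frame(id = seq_along(xs),
                       parent = c(-1L, seq_along(xs)[-length(xs)]),
                       x = xs, y = ys, z = 0, radius = 1))
}

# tree with one bifurcation: trunk to (len, 0), branches to two tips
make_forked_tree <- function(trunk = 100, branch = 60) {
  n1 <- trunk / 10 + 1
  xs <- seq(0, trunk, by = 10)
  nodes <- data.frame(id = seq_len(n1), parent = c(-1L, seq_len(n1 - 1)),
                      x = xs, y = 0, z = 0, radius = 1)
  for (dy in c(-1, 1)) {
    bx <- seq(trunk + 10, trunk + branch, by = 10)
    ids <- nrow(nodes) + seq_along(bx)
    nodes <- rbind(nodes, data.frame(
      id = ids, parent = c(n1, ids[-length(ids)]),
      x = bx, y = dy * seq_along(bx) * 5, z = 0, radius = 1))
  }
  axon_tree(nodes)
}
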