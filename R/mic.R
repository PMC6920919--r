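#' Maximal Information Coefficient (MIC)
#'
#' MIC between two numeric vectors: the maximum, over grid shapes (a, b)
#' with a, b >= 2 and a * b not exceeding the grid budget, of the largest
#' mutual information achievable by an a x b grid drawn on the data,
#' normalised by log2(min(a, b)). Cuts can only fall between distinct data
#' values, so tied observations always share a grid cell. The grid budget
#' is n^alpha, floored at 4 so that a 2 x 2 grid is always admissible.
#'
#' Two search strategies are provided. `"exact"` (the default) maximises
#' the grid mutual information exactly: for every admissible shape it
#' enumerates all row partitions and finds the optimal column partition by
#' dynamic programming, exploiting that mutual information with a fixed row
#' partition is additive over column segments. This is exact and fast at
#' the sample sizes community tables produce (tens of samples), where the
#' budget keeps grids small. `"approx"` is the classical MINE heuristic:
#' equipartition one axis, optimise the other by the same dynamic
#' programme over clump boundaries (capped at `c * a` superclumps), in both
#' orientations, taking the better.
#'
#' @param x,y Numeric vectors of equal length, n >= 5.
#' @param alpha Grid budget exponent (default 0.6).
#' @param c Superclump factor for the `"approx"` method (default 15).
#' @param method `"exact"` or `"approx"`.
#' @return The MIC score in \[0, 1\]. A constant vector yields 0 with a
#'   warning.
#' @export
mic <- function(x, y, alpha = 0.6, c = 15, method = c("exact", "approx")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector; MIC is 0")
    return(0)
  }
  B <- max(n^alpha, 4)
  best <- 0
  for (b in 2:floor(B / 2)) {
    for (a in 2:floor(B / b)) {
      I <- if (method == "exact") {
        max_grid_info_exact(x, y, a, b)
      } else {
        max_grid_info_approx(x, y, a, b, c)
      }
      if (!is.na(I)) best <- max(best, I / log2(min(a, b)))
    }
  }
  min(max(best, 0), 1)
}

# Shannon entropy (bits) of a count vector
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# positions (in sorted order) after which a cut may be placed: value changes
gap_positions <- function(v_sorted) which(diff(v_sorted) > 0)

# Exact maximal mutual information of an a x b grid on (x, y): enumerate
# all b-part row partitions of y; for each, the optimal a-part column
# partition of x follows by dynamic programming, since
# I = H(rows) - sum_cols (n_col/n) H(rows | col) is additive over columns.
max_grid_info_exact <- function(x, y, a, b) {
  n <- length(x)
  oy <- order(y)
  ygaps <- gap_positions(y[oy])
  ox <- order(x)
  xgaps <- gap_positions(x[ox])
  if (length(ygaps) < b - 1 || length(xgaps) < a - 1) return(NA_real_)

  pos_y <- integer(n)
  pos_y[oy] <- seq_len(n)          # rank position of each point on y
  rows_combos <- utils::combn(ygaps, b - 1)

  best <- -Inf
  for (kk in seq_len(ncol(rows_combos))) {
    cuts <- rows_combos[, kk]
    row_id <- findInterval(pos_y, cuts + 0.5) + 1L
    I <- optimize_columns(row_id[ox], xgaps, a, b, n)
    if (!is.na(I) && I > best) best <- I
  }
  if (is.infinite(best)) NA_real_ else best
}

# Dynamic programme: given the row id of each point in x-sorted order and
# the admissible cut positions, the a-column partition maximising
# I = H(row marginal) + sum_cols -(n_col/n) H(rows within col)
optimize_columns <- function(rows_x, cut_pos, a, b, n) {
  if (length(cut_pos) < a - 1) return(NA_real_)
  # prefix row counts: pref[r, i+1] = #points among first i with row r
  pref <- matrix(0L, b, n + 1L)
  for (i in seq_len(n)) {
    pref[, i + 1L] <- pref[, i]
    pref[rows_x[i], i + 1L] <- pref[rows_x[i], i + 1L] + 1L
  }
  seg_score <- function(e1, e2) {
    cnt <- pref[, e2 + 1L] - pref[, e1 + 1L]
    -(sum(cnt) / n) * entropy_bits(cnt)
  }
  ends <- c(cut_pos, n)
  m <- length(ends)
  # F[k, e]: best score of a k-column partition of (0, ends[e]]
  F <- matrix(-Inf, a, m)
  for (e in seq_len(m)) F[1, e] <- seg_score(0L, ends[e])
  if (a >= 2) {
    for (k in 2:a) {
      for (e in k:m) {
        prev <- (k - 1):(e - 1)
        F[k, e] <- max(F[k - 1, prev] +
                         vapply(prev, function(pp) seg_score(ends[pp], ends[e]),
                                numeric(1)))
      }
    }
  }
  if (is.infinite(F[a, m])) return(NA_real_)
  entropy_bits(pref[, n + 1L]) + F[a, m]
}

# MINE-style equipartition of a vector into (at most) b groups, keeping
# tied values together; returns a group id per point
equipartition_axis <- function(v, b) {
  n <- length(v)
  o <- order(v)
  vs <- v[o]
  runs <- rle(vs)$lengths
  grp_of_run <- integer(length(runs))
  curr <- 1L
  curr_size <- 0
  assigned <- 0
  desired <- n / b
  for (r in seq_along(runs)) {
    s <- runs[r]
    if (curr_size != 0 &&
        abs(curr_size + s - desired) >= abs(curr_size - desired) &&
        curr < b) {
      curr <- curr + 1L
      curr_size <- 0
      desired <- (n - assigned) / (b - curr + 1)
    }
    grp_of_run[r] <- curr
    curr_size <- curr_size + s
    assigned <- assigned + s
  }
  grp_sorted <- rep(grp_of_run, runs)
  grp <- integer(n)
  grp[o] <- grp_sorted
  grp
}

# MINE heuristic for one grid shape and one orientation: equipartition y
# into b rows, optimise x into a columns over clump boundaries
approx_one_orientation <- function(x, y, a, b, c) {
  n <- length(x)
  row_id <- equipartition_axis(y, b)
  b_eff <- max(row_id)
  if (b_eff < 2) return(NA_real_)
  ox <- order(x)
  rows_x <- row_id[ox]
  xv <- x[ox]
  # clumps: maximal runs of same-row points; ties on x always merged
  boundary <- which(diff(xv) > 0 & diff(rows_x) != 0)
  value_gaps <- gap_positions(xv)
  boundary <- intersect(value_gaps, boundary)
  if (length(boundary) + 1 > c * a) {
    # superclumps: thin the boundary set towards c*a roughly equal groups
    keep_n <- max(a - 1, floor(c * a) - 1)
    idx <- unique(round(seq(1, length(boundary), length.out = keep_n)))
    boundary <- boundary[idx]
  }
  if (length(boundary) < a - 1) boundary <- value_gaps
  if (length(boundary) < a - 1) return(NA_real_)
  optimize_columns(rows_x, boundary, a, max(b_eff, b), n)
}

max_grid_info_approx <- function(x, y, a, b, c) {
  i1 <- approx_one_orientation(x, y, a, b, c)
  i2 <- approx_one_orientation(y, x, b, a, c)
  if (is.na(i1) && is.na(i2)) return(NA_real_)
  max(i1, i2, na.rm = TRUE)
}

#' Exhaustive-grid MIC (reference implementation)
#'
#' Brute-force MIC used as an independent validation oracle: for every
#' admissible grid shape it enumerates all row partitions and all column
#' partitions outright and computes the mutual information of each
#' contingency table directly. Exponential in the grid size; intended for
#' small n only.
#'
#' @inheritParams mic
#' @return The MIC score in \[0, 1\].
#' @export
mic_exhaustive <- function(x, y, alpha = 0.6) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(0)
  B <- max(n^alpha, 4)
  oy <- order(y); ygaps <- gap_positions(y[oy])
  ox <- order(x); xgaps <- gap_positions(x[ox])
  pos_y <- integer(n); pos_y[oy] <- seq_len(n)
  pos_x <- integer(n); pos_x[ox] <- seq_len(n)

  table_mi <- function(tab) {
    nn <- sum(tab)
    hx <- entropy_bits(rowSums(tab))
    hy <- entropy_bits(colSums(tab))
    hxy <- entropy_bits(as.vector(tab))
    hx + hy - hxy
  }
  best <- 0
  for (b in 2:floor(B / 2)) {
    if (length(ygaps) < b - 1) next
    rc <- utils::combn(ygaps, b - 1)
    for (a in 2:floor(B / b)) {
      if (length(xgaps) < a - 1) next
      cc <- utils::combn(xgaps, a - 1)
      norm <- log2(min(a, b))
      for (i in seq_len(ncol(rc))) {
        row_id <- findInterval(pos_y, rc[, i] + 0.5) + 1L
        for (j in seq_len(ncol(cc))) {
          col_id <- findInterval(pos_x, cc[, j] + 0.5) + 1L
          tab <- matrix(0L, a, b)
          for (p in seq_len(n)) {
            tab[col_id[p], row_id[p]] <- tab[col_id[p], row_id[p]] + 1L
          }
          val <- table_mi(tab) / norm
          if (val > best) best <- val
        }
      }
    }
  }
  min(max(best, 0), 1)
}

#' Permutation p-value for a MIC score
#'
#' p = (1 + #\{permuted MIC >= observed\}) / (1 + n_perm) under random
#' permutations of `y` with a seeded generator.
#'
#' @inheritParams mic
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A list: `mic` (observed score) and `p` (permutation p-value,
#'   always in (0, 1\]).
#' @export
mic_pvalue <- function(x, y, n_perm = 999, seed = 0, alpha = 0.6, c = 15,
                       method = "exact") {
  if (n_perm < 99) stop("n_perm must be at least 99")
  obs <- mic(x, y, alpha = alpha, c = c, method = method)
  perm_ge <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      suppressWarnings(mic(x, sample(y), alpha = alpha, c = c, method = method))
    }, numeric(1)) >= obs)
  })
  list(mic = obs, p = (1 + perm_ge) / (1 + n_perm))
}
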