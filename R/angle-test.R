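# Codon-specific Ramachandran comparison.
#
# Angle distributions are estimated with a periodic (wrapped) Gaussian
# kernel density on a regular G x G grid over [-180, 180)^2. The distance
# statistic DDist between two codons' distributions is the total-variation
# distance between their grid densities (bounded in [0, 1]). Significance
# comes from a label permutation between the two codon groups; q-values
# from Benjamini-Hochberg.
#
# Implementation note: points are spread onto the grid by periodic
# bilinear ("linear binning") assignment and the binned mass is convolved
# with the wrapped Gaussian kernel by 2-D FFT — the standard fast KDE
# construction, exactly periodic by circular convolution. Because the
# smoothing is linear, the permutation loop only re-bins group labels and
# runs one FFT per permutation.

#' Configuration for the codon-pair angle test
#'
#' @param bandwidth_deg Gaussian kernel bandwidth in degrees (default 15;
#'   small enough to resolve Ramachandran basins, large enough to avoid
#'   extreme over-fitting).
#' @param grid_size grid resolution G per axis (default 64; minimum 8).
#' @param n_perm number of label permutations (default 999). `0` computes
#'   distances only, without p-values.
#' @param min_n minimum records per codon per (aa, ss) stratum; below it a
#'   pair is reported untested rather than tested on noise (default 50).
#' @param alpha significance level for BH-adjusted q-values (default 0.05).
#' @param seed integer seed.
#' @return list of class `angle_test_config`.
#' @export
angle_test_config <- function(bandwidth_deg = 15, grid_size = 64,
                              n_perm = 999, min_n = 50, alpha = 0.05,
                              seed = 1) {
  stopifnot(bandwidth_deg > 0, n_perm >= 0, min_n >= 1)
  if (grid_size < 8) stop("grid_size must be >= 8", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  structure(list(bandwidth_deg = bandwidth_deg, grid_size = grid_size,
                 n_perm = n_perm, min_n = min_n, alpha = alpha, seed = seed),
            class = "angle_test_config")
}

# Periodic bilinear binning of (phi, psi) points onto a G x G grid.
# Returns list(idx = n x 4 cell indices, w = n x 4 weights); the binned
# histogram of a subset of rows is .bin_accumulate(idx, w, rows, G).
.bin_torus_parts <- function(phi, psi, G) {
  h <- 360 / G
  u <- (phi + 180) / h - 0.5
  v <- (psi + 180) / h - 0.5
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  i0 <- i0 %% G; j0 <- j0 %% G
  i1 <- (i0 + 1) %% G; j1 <- (j0 + 1) %% G
  idx <- cbind(j0 * G + i0 + 1, j0 * G + i1 + 1,
               j1 * G + i0 + 1, j1 * G + i1 + 1)
  w <- cbind((1 - fu) * (1 - fv), fu * (1 - fv), (1 - fu) * fv, fu * fv)
  list(idx = idx, w = w)
}

.bin_accumulate <- function(parts, rows, G) {
  .bin_group_cpp(parts$idx, parts$w, as.integer(rows), as.integer(G))
}

# Pure-R reference implementation of the binning accumulator (kept as an
# independent check on the compiled version).
.bin_accumulate_r <- function(parts, rows, G) {
  H <- numeric(G * G)
  s <- rowsum(c(parts$w[rows, , drop = FALSE]),
              c(parts$idx[rows, , drop = FALSE]))
  H[as.integer(rownames(s))] <- s[, 1L]
  matrix(H, G, G)
}

# Wrapped Gaussian kernel on the grid (sums to 1), zero offset at [1,1].
.torus_kernel <- function(bandwidth_deg, G) {
  h <- 360 / G
  d <- h * (0:(G - 1))
  k1 <- numeric(G)
  for (r in -3:3) k1 <- k1 + stats::dnorm(d + 360 * r, 0, bandwidth_deg)
  K <- outer(k1, k1)
  K / sum(K)
}

#' Periodic kernel density estimate on the (phi, psi) torus
#'
#' Wrapped-Gaussian KDE on a regular grid over `[-180, 180)^2`: mass near
#' one edge correctly leaks to the opposite edge. The returned grid
#' integrates to 1 (`sum(grid) * cell_area == 1`).
#'
#' @param angles data.frame with columns `phi_deg`, `psi_deg`, or a
#'   two-column matrix.
#' @param bandwidth_deg kernel bandwidth in degrees.
#' @param grid_size grid resolution per axis (>= 8).
#' @return object of class `torus_density`: list with `grid`
#'   (`grid_size` x `grid_size`, phi indexes rows), `cell_area` in square
#'   degrees, `centers` of grid cells, `bandwidth_deg`, `n` points used.
#' @export
torus_kde <- function(angles, bandwidth_deg = 15, grid_size = 64) {
  stopifnot(bandwidth_deg > 0)
  if (grid_size < 8) stop("grid_size must be >= 8", call. = FALSE)
  x <- if (is.matrix(angles)) angles else
    cbind(angles$phi_deg, angles$psi_deg)
  if (is.null(dim(x)) || nrow(x) < 1L) stop("at least one point required",
                                            call. = FALSE)
  phi <- wrap_degrees(x[, 1]); psi <- wrap_degrees(x[, 2])
  G <- grid_size
  parts <- .bin_torus_parts(phi, psi, G)
  H <- .bin_accumulate(parts, seq_along(phi), G)
  K <- .torus_kernel(bandwidth_deg, G)
  sm <- Re(stats::fft(stats::fft(H) * stats::fft(K), inverse = TRUE)) / G^2
  sm[sm < 0] <- 0
  ca <- (360 / G)^2
  structure(list(grid = sm / (sum(sm) * ca),
                 grid_size = G, cell_area = ca,
                 centers = -180 + (seq_len(G) - 0.5) * (360 / G),
                 bandwidth_deg = bandwidth_deg, n = length(phi)),
            class = "torus_density")
}

#' @export
print.torus_density <- function(x, ...) {
  cat(sprintf("torus_density: %dx%d grid, bandwidth %g deg, n = %d\n",
              x$grid_size, x$grid_size, x$bandwidth_deg, x$n))
  invisible(x)
}

#' Total-variation distance between two torus densities (DDist)
#'
#' `0.5 * sum(|d1 - d2|) * cell_area`; symmetric, 0 iff the grids are
#' identical, at most 1.
#'
#' @param d1,d2 `torus_density` objects on the same grid.
#' @return nonnegative scalar in `[0, 1]`.
#' @export
ddist <- function(d1, d2) {
  if (d1$grid_size != d2$grid_size) stop("grid sizes differ", call. = FALSE)
  0.5 * sum(abs(d1$grid - d2$grid)) * d1$cell_area
}

# Fast TV distance between the KDEs of two disjoint row sets sharing one
# binning. Kf is fft of the (sum-1) kernel. Exploits linearity: TV =
# 0.5 * sum |ifft(fft(H_a/n_a - H_b/n_b) * Kf)|.
.tv_between_groups <- function(parts, rows_a, rows_b, G, Kf) {
  Ha <- .bin_accumulate(parts, rows_a, G)
  Hb <- .bin_accumulate(parts, rows_b, G)
  Hd <- Ha / length(rows_a) - Hb / length(rows_b)
  D <- Re(stats::fft(stats::fft(Hd) * Kf, inverse = TRUE)) / G^2
  0.5 * sum(abs(D))
}

#' Permutation test for one synonymous codon pair
#'
#' Compares the (phi, psi) distributions of two synonymous codons within
#' one (amino acid, secondary structure) stratum. The observed statistic
#' is the total-variation distance between the two wrapped-kernel
#' densities; the null distribution comes from `n_perm` random
#' reassignments of codon labels to records (group sizes preserved), and
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param records dihedral-record data.frame (see [validate_records()]).
#' @param aa amino acid (or family label).
#' @param ss secondary-structure class.
#' @param codon_a,codon_b the two synonymous codons (must differ; use
#'   [self_distance()] for a codon against itself).
#' @param config an [angle_test_config()].
#' @return one-row data.frame: `aa, ss, codon_a, codon_b, n_a, n_b, ddist,
#'   p_value, tested`. When either codon has fewer than `min_n` records
#'   the pair is flagged untested (`tested = FALSE`, statistics `NA`).
#' @export
pair_test <- function(records, aa, ss, codon_a, codon_b,
                      config = angle_test_config()) {
  if (codon_a == codon_b) {
    stop("codon_a == codon_b: use self_distance() for self-comparison",
         call. = FALSE)
  }
  sub <- records[records$aa == aa & records$ss == ss &
                   records$codon %in% c(codon_a, codon_b), , drop = FALSE]
  n_a <- sum(sub$codon == codon_a)
  n_b <- sum(sub$codon == codon_b)
  if (n_a < config$min_n || n_b < config$min_n) {
    return(data.frame(aa = aa, ss = ss, codon_a = codon_a, codon_b = codon_b,
                      n_a = n_a, n_b = n_b, ddist = NA_real_,
                      p_value = NA_real_, tested = FALSE))
  }
  set.seed(as.integer(config$seed))
  G <- config$grid_size
  parts <- .bin_torus_parts(wrap_degrees(sub$phi_deg),
                            wrap_degrees(sub$psi_deg), G)
  Kf <- stats::fft(.torus_kernel(config$bandwidth_deg, G))
  is_a <- sub$codon == codon_a
  obs <- .tv_between_groups(parts, which(is_a), which(!is_a), G, Kf)
  p <- NA_real_
  if (config$n_perm > 0) {
    n <- nrow(sub)
    Hpool <- .bin_accumulate(parts, seq_len(n), G)
    exceed <- 0L
    for (b in seq_len(config$n_perm)) {
      ga <- sample.int(n, n_a)
      Ha <- .bin_accumulate(parts, ga, G)
      Hd <- Ha / n_a - (Hpool - Ha) / n_b
      D <- Re(stats::fft(stats::fft(Hd) * Kf, inverse = TRUE)) / G^2
      if (0.5 * sum(abs(D)) >= obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + config$n_perm)
  }
  data.frame(aa = aa, ss = ss, codon_a = codon_a, codon_b = codon_b,
             n_a = n_a, n_b = n_b, ddist = obs, p_value = p, tested = TRUE)
}

#' Self-comparison noise baseline for one codon
#'
#' Randomly halves a codon's own records `n_splits` times and records the
#' total-variation distance between the two half-KDEs. Because the halves
#' come from one distribution, the mean self-distance is a pure-noise
#' baseline for that codon and stratum.
#'
#' @param records dihedral-record data.frame.
#' @param aa amino acid (family label).
#' @param ss secondary-structure class.
#' @param codon the codon.
#' @param n_splits number of random half-splits.
#' @param config an [angle_test_config()] (`min_n` applies per half).
#' @return numeric vector of length `n_splits` (empty if `n_splits = 0`),
#'   or `NULL` with attribute handling when fewer than `2 * min_n` records
#'   exist (flagged untested via attribute `tested = FALSE`).
#' @export
self_distance <- function(records, aa, ss, codon, n_splits = 10,
                          config = angle_test_config()) {
  sub <- records[records$aa == aa & records$ss == ss &
                   records$codon == codon, , drop = FALSE]
  n <- nrow(sub)
  if (n < 2 * config$min_n) {
    out <- numeric(0)
    attr(out, "tested") <- FALSE
    return(out)
  }
  if (n_splits == 0) {
    out <- numeric(0)
    attr(out, "tested") <- TRUE
    return(out)
  }
  set.seed(as.integer(config$seed))
  G <- config$grid_size
  parts <- .bin_torus_parts(wrap_degrees(sub$phi_deg),
                            wrap_degrees(sub$psi_deg), G)
  Kf <- stats::fft(.torus_kernel(config$bandwidth_deg, G))
  half <- n %/% 2L
  out <- vapply(seq_len(n_splits), function(s) {
    ga <- sample.int(n, half)
    .tv_between_groups(parts, ga, seq_len(n)[-ga], G, Kf)
  }, numeric(1))
  attr(out, "tested") <- TRUE
  out
}

#' Benjamini-Hochberg correction across a codon-pair results table
#'
#' Adds `q_value` and `significant` columns. Untested pairs are excluded
#' from the correction and keep `NA` q-values.
#'
#' @param results data.frame with `p_value` and `tested` columns (e.g.
#'   rows from [pair_test()] or [run_all_pairs()]).
#' @param alpha FDR level in (0, 1).
#' @return `results` with `q_value` and `significant` columns.
#' @export
multiple_testing <- function(results, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  results$q_value <- NA_real_
  results$significant <- FALSE
  tested <- which(results$tested & !is.na(results$p_value))
  if (length(tested)) {
    q <- stats::p.adjust(results$p_value[tested], method = "BH")
    results$q_value[tested] <- q
    results$significant[tested] <- q <= alpha
  }
  results
}

#' Run the codon-pair angle test over all synonymous pairs and strata
#'
#' Iterates over every synonymous family with at least two codons, every
#' secondary-structure class, and every unordered codon pair, in
#' deterministic (family, ss, pair) lexicographic order. Each pair draws
#' its own seed from `config$seed` up front, so the full table is
#' reproducible and independent of evaluation order. BH q-values are
#' computed across the whole table.
#'
#' @param records dihedral-record data.frame.
#' @param config an [angle_test_config()].
#' @param code a [genetic_code()] object.
#' @return data.frame with columns `aa, ss, codon_a, codon_b, n_a, n_b,
#'   ddist, p_value, q_value, significant, tested`.
#' @export
run_all_pairs <- function(records, config = angle_test_config(),
                          code = genetic_code()) {
  records <- validate_records(records, code)
  fams <- names(code$families)[lengths(code$families) >= 2L]
  grid <- list()
  for (fam in fams) {
    codons <- code$families[[fam]]
    prs <- utils::combn(codons, 2L)
    for (ss in SS_CLASSES) {
      for (k in seq_len(ncol(prs))) {
        grid[[length(grid) + 1L]] <- list(fam = fam, ss = ss,
                                          a = prs[1, k], b = prs[2, k])
      }
    }
  }
  seeds <- derive_seeds(config$seed, length(grid))
  # family label, not raw aa, keys the test strata (serine splitting)
  fam_aa <- vapply(fams, function(f) code$table[[code$families[[f]][1]]],
                   character(1))
  rec_fam <- code$family_of[records$codon]
  out <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    g <- grid[[k]]
    cfg_k <- config
    cfg_k$seed <- seeds[k]
    sub <- records[rec_fam == g$fam, , drop = FALSE]
    sub$aa <- rep(g$fam, nrow(sub))
    out[[k]] <- pair_test(sub, g$fam, g$ss, g$a, g$b, cfg_k)
  }
  res <- do.call(rbind, out)
  multiple_testing(res, config$alpha)
}

#' Mean self-distance per (family, ss, codon)
#'
#' Companion to [run_all_pairs()]: for every codon with enough records in
#' a stratum, the mean total-variation distance across `n_splits` random
#' half-splits — the noise baseline used by
#' [noise_signal_correlation()].
#'
#' @param records dihedral-record data.frame.
#' @param n_splits half-splits per codon.
#' @param config an [angle_test_config()].
#' @param code a [genetic_code()] object.
#' @return data.frame `aa, ss, codon, n, mean_self_dist, tested`.
#' @export
self_distance_table <- function(records, n_splits = 10,
                                config = angle_test_config(),
                                code = genetic_code()) {
  records <- validate_records(records, code)
  rec_fam <- code$family_of[records$codon]
  fams <- names(code$families)
  grid <- list()
  for (fam in fams) {
    for (ss in SS_CLASSES) {
      for (cd in code$families[[fam]]) {
        grid[[length(grid) + 1L]] <- list(fam = fam, ss = ss, codon = cd)
      }
    }
  }
  seeds <- derive_seeds(config$seed, length(grid))
  out <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    g <- grid[[k]]
    cfg_k <- config
    cfg_k$seed <- seeds[k]
    sub <- records[rec_fam == g$fam, , drop = FALSE]
    sub$aa <- rep(g$fam, nrow(sub))
    d <- self_distance(sub, g$fam, g$ss, g$codon, n_splits, cfg_k)
    out[[k]] <- data.frame(aa = g$fam, ss = g$ss, codon = g$codon,
                           n = sum(sub$ss == g$ss & sub$codon == g$codon),
                           mean_self_dist = if (length(d)) mean(d) else NA_real_,
                           tested = isTRUE(attr(d, "tested")))
  }
  do.call(rbind, out)
}
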