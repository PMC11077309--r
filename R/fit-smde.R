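# Metropolis-within-Gibbs sampler for the SMDE codon-usage model.
#
# Parameters: per non-reference codon, a mutation-bias offset dM and a
# selection offset dEta (reference codons pinned at 0); per gene, a log
# expression value. The likelihood is the per-gene multinomial over each
# synonymous family. Identifiability: phi is renormalised to geometric
# mean 1 after every sweep, with dEta rescaled inversely so the
# likelihood is untouched.
#
# Updates per sweep:
#   * each non-reference codon's dM and dEta get a Gaussian random-walk
#     proposal, accepted against the family's likelihood plus a Normal
#     prior;
#   * all log-phi values get simultaneous independent proposals; because
#     the likelihood factorises over genes, accept/reject is vectorised
#     per gene.
# Proposal scales adapt during burn-in towards ~0.3 acceptance.

# Family log-likelihood over all genes (C: genes x n counts).
.fam_ll <- function(C, rowTot, dM, dEta, phi) {
  A <- -outer(phi, dEta)
  A <- sweep(A, 2, dM)
  m <- A[cbind(seq_len(nrow(A)), max.col(A, "first"))]
  logZ <- log(rowSums(exp(A - m))) + m
  sum(C * A) - sum(rowTot * logZ)
}

# Per-gene log-likelihood vector for one family.
.fam_ll_by_gene <- function(C, rowTot, dM, dEta, phi) {
  A <- -outer(phi, dEta)
  A <- sweep(A, 2, dM)
  m <- A[cbind(seq_len(nrow(A)), max.col(A, "first"))]
  logZ <- log(rowSums(exp(A - m))) + m
  rowSums(C * A) - rowTot * logZ
}

#' Fit the SMDE codon-usage model by MCMC
#'
#' Metropolis-within-Gibbs on the multinomial likelihood implied by the
#' SMDE codon-probability formula, for parameter recovery on synthetic
#' data. Priors: `deltaM`, `deltaEta` ~ Normal(0, prior_sd^2);
#' `log(phi)` ~ Normal(0, prior_sdlog_phi^2). Expression is renormalised
#' to geometric mean 1 each sweep (with `deltaEta` rescaled inversely),
#' which fixes the phi/deltaEta scale non-identifiability.
#'
#' Families never observed in the counts are skipped with a warning;
#' single-codon families carry no parameters.
#'
#' @param counts genes x 61 sense-codon count matrix from [codon_counts()].
#' @param code a [genetic_code()] object.
#' @param n_iter total sweeps (including burn-in).
#' @param burn_in sweeps discarded (during which proposal scales adapt).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param prior_sd prior standard deviation for deltaM and deltaEta.
#' @param prior_sdlog_phi prior standard deviation of log phi.
#' @param init_scale initial random-walk proposal standard deviation.
#' @param seed integer seed.
#' @param verbose print progress every 200 sweeps.
#' @return object of class `smde_fit`: list with `codon_summary`
#'   (data.frame: family, codon, is_reference, posterior mean/sd/2.5%/97.5%
#'   for deltaM and deltaEta), `phi_summary` (gene_id, mean/sd/quantiles of
#'   phi), `chains` (matrices of kept draws), and `acceptance` rates.
#' @export
fit_smde <- function(counts, code = genetic_code(),
                     n_iter = 1500, burn_in = 500, thin = 2,
                     prior_sd = 1, prior_sdlog_phi = 2,
                     init_scale = 0.1, seed = 1, verbose = FALSE) {
  if (nrow(counts) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (init_scale <= 0) stop("proposal scale must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  G <- nrow(counts)
  gene_ids <- rownames(counts)

  fams <- list()
  for (fam in names(code$families)) {
    codons <- code$families[[fam]]
    if (length(codons) < 2L) next
    C <- counts[, codons, drop = FALSE]
    storage.mode(C) <- "double"
    if (sum(C) == 0) {
      warning("family ", fam, " never observed; skipped")
      next
    }
    ref_idx <- match(code$reference[[fam]], codons)
    # moment initialisation for dM from pooled frequencies
    tot <- colSums(C) + 0.5
    dM0 <- -log(tot / tot[ref_idx])
    dM0[ref_idx] <- 0
    fams[[fam]] <- list(codons = codons, C = C, rowTot = rowSums(C),
                        ref = ref_idx, free = setdiff(seq_along(codons), ref_idx),
                        dM = unname(dM0), dEta = numeric(length(codons)))
  }
  if (!length(fams)) stop("no multi-codon family observed", call. = FALSE)

  lphi <- numeric(G)
  # proposal scales
  sc <- lapply(fams, function(f)
    list(dM = rep(init_scale, length(f$free)),
         dEta = rep(init_scale, length(f$free))))
  sc_phi <- rep(init_scale * 2, G)
  acc <- lapply(fams, function(f)
    list(dM = rep(0, length(f$free)), dEta = rep(0, length(f$free))))
  acc_phi <- rep(0, G)
  n_prop <- 0L
  adapt_every <- 50L

  # cached per-family log-likelihoods
  ll_fam <- vapply(fams, function(f)
    .fam_ll(f$C, f$rowTot, f$dM, f$dEta, exp(lphi)), numeric(1))

  keep <- seq(burn_in + 1L, n_iter)
  keep <- keep[(seq_along(keep) - 1L) %% thin == 0L]
  n_keep <- length(keep)
  free_codons <- unlist(lapply(fams, function(f) f$codons[f$free]),
                        use.names = FALSE)
  chain_dM <- matrix(NA_real_, n_keep, length(free_codons),
                     dimnames = list(NULL, free_codons))
  chain_dEta <- chain_dM
  chain_phi <- matrix(NA_real_, n_keep, G, dimnames = list(NULL, gene_ids))
  k_out <- 0L

  for (it in seq_len(n_iter)) {
    phi <- exp(lphi)
    n_prop <- n_prop + 1L
    # --- codon parameter updates, family by family ---
    for (fam in names(fams)) {
      f <- fams[[fam]]
      for (j in seq_along(f$free)) {
        i <- f$free[j]
        # dM
        prop <- f$dM
        prop[i] <- prop[i] + stats::rnorm(1, 0, sc[[fam]]$dM[j])
        ll_new <- .fam_ll(f$C, f$rowTot, prop, f$dEta, phi)
        lr <- ll_new - ll_fam[[fam]] +
          stats::dnorm(prop[i], 0, prior_sd, log = TRUE) -
          stats::dnorm(f$dM[i], 0, prior_sd, log = TRUE)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          f$dM <- prop; ll_fam[[fam]] <- ll_new
          acc[[fam]]$dM[j] <- acc[[fam]]$dM[j] + 1
        }
        # dEta
        prop <- f$dEta
        prop[i] <- prop[i] + stats::rnorm(1, 0, sc[[fam]]$dEta[j])
        ll_new <- .fam_ll(f$C, f$rowTot, f$dM, prop, phi)
        lr <- ll_new - ll_fam[[fam]] +
          stats::dnorm(prop[i], 0, prior_sd, log = TRUE) -
          stats::dnorm(f$dEta[i], 0, prior_sd, log = TRUE)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          f$dEta <- prop; ll_fam[[fam]] <- ll_new
          acc[[fam]]$dEta[j] <- acc[[fam]]$dEta[j] + 1
        }
      }
      fams[[fam]] <- f
    }
    # --- phi updates, vectorised over genes ---
    lphi_new <- lphi + stats::rnorm(G, 0, sc_phi)
    llg_old <- numeric(G); llg_new <- numeric(G)
    phi <- exp(lphi); phi_new <- exp(lphi_new)
    for (fam in names(fams)) {
      f <- fams[[fam]]
      llg_old <- llg_old + .fam_ll_by_gene(f$C, f$rowTot, f$dM, f$dEta, phi)
      llg_new <- llg_new + .fam_ll_by_gene(f$C, f$rowTot, f$dM, f$dEta, phi_new)
    }
    lr <- llg_new - llg_old +
      stats::dnorm(lphi_new, 0, prior_sdlog_phi, log = TRUE) -
      stats::dnorm(lphi, 0, prior_sdlog_phi, log = TRUE)
    take <- log(stats::runif(G)) < lr
    lphi[take] <- lphi_new[take]
    acc_phi <- acc_phi + take
    # --- mode-flip move ---
    # The posterior has an approximate reflection mode
    # (lphi -> -lphi, dEta -> -dEta, dM -> dM + 2 dEta): exact to first
    # order in lphi, so a chain started symmetrically can settle in the
    # mirrored mode. A deterministic involution MH proposal (unit
    # Jacobian) lets the chain jump to the dominant mode.
    {
      phi_f <- exp(-lphi)
      ll_new_fam <- numeric(length(fams)); names(ll_new_fam) <- names(fams)
      dprior <- 0
      for (fam in names(fams)) {
        f <- fams[[fam]]
        dM_f <- f$dM + 2 * f$dEta
        ll_new_fam[[fam]] <- .fam_ll(f$C, f$rowTot, dM_f, -f$dEta, phi_f)
        dprior <- dprior +
          sum(stats::dnorm(dM_f[f$free], 0, prior_sd, log = TRUE)) -
          sum(stats::dnorm(f$dM[f$free], 0, prior_sd, log = TRUE))
      }
      lr <- sum(ll_new_fam) - sum(ll_fam) + dprior
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        lphi <- -lphi
        for (fam in names(fams)) {
          fams[[fam]]$dM <- fams[[fam]]$dM + 2 * fams[[fam]]$dEta
          fams[[fam]]$dEta <- -fams[[fam]]$dEta
        }
        ll_fam <- ll_new_fam
      }
    }
    # --- renormalise: phi geometric mean 1, dEta rescaled inversely ---
    shift <- mean(lphi)
    if (abs(shift) > 0) {
      scale_fac <- exp(shift)
      lphi <- lphi - shift
      for (fam in names(fams)) fams[[fam]]$dEta <- fams[[fam]]$dEta * scale_fac
      phi <- exp(lphi)
      ll_fam <- vapply(fams, function(f)
        .fam_ll(f$C, f$rowTot, f$dM, f$dEta, phi), numeric(1))
    }
    # --- adaptation during burn-in ---
    if (it <= burn_in && it %% adapt_every == 0L) {
      for (fam in names(fams)) {
        r_dM <- acc[[fam]]$dM / adapt_every
        r_dE <- acc[[fam]]$dEta / adapt_every
        sc[[fam]]$dM <- sc[[fam]]$dM * exp(r_dM - 0.3)
        sc[[fam]]$dEta <- sc[[fam]]$dEta * exp(r_dE - 0.3)
        acc[[fam]]$dM[] <- 0; acc[[fam]]$dEta[] <- 0
      }
      sc_phi <- sc_phi * exp(acc_phi / adapt_every - 0.3)
      acc_phi[] <- 0
      n_prop <- 0L
    }
    if (it %in% keep) {
      k_out <- k_out + 1L
      chain_dM[k_out, ] <- unlist(lapply(fams, function(f) f$dM[f$free]),
                                  use.names = FALSE)
      chain_dEta[k_out, ] <- unlist(lapply(fams, function(f) f$dEta[f$free]),
                                    use.names = FALSE)
      chain_phi[k_out, ] <- exp(lphi)
    }
    if (verbose && it %% 200L == 0L) {
      message(sprintf("sweep %d/%d  loglik %.1f", it, n_iter, sum(ll_fam)))
    }
  }

  summarize <- function(chain) {
    data.frame(mean = colMeans(chain),
               sd = apply(chain, 2, stats::sd),
               q2.5 = apply(chain, 2, stats::quantile, 0.025),
               q97.5 = apply(chain, 2, stats::quantile, 0.975))
  }
  fam_of <- unlist(lapply(names(fams), function(fam)
    rep(fam, length(fams[[fam]]$free))), use.names = FALSE)
  sm <- summarize(chain_dM); se <- summarize(chain_dEta)
  codon_summary <- data.frame(
    family = fam_of, codon = free_codons,
    deltaM_mean = sm$mean, deltaM_sd = sm$sd,
    deltaM_q2.5 = sm$q2.5, deltaM_q97.5 = sm$q97.5,
    deltaEta_mean = se$mean, deltaEta_sd = se$sd,
    deltaEta_q2.5 = se$q2.5, deltaEta_q97.5 = se$q97.5,
    row.names = NULL)
  sp <- summarize(chain_phi)
  phi_summary <- data.frame(gene_id = gene_ids, phi_mean = sp$mean,
                            phi_sd = sp$sd, phi_q2.5 = sp$q2.5,
                            phi_q97.5 = sp$q97.5, row.names = NULL)
  # acc_phi was last reset at the final burn-in adaptation
  post_phi_rate <- acc_phi / max(1L, n_iter - (burn_in %/% adapt_every) * adapt_every)
  post_phi_rate <- pmin(post_phi_rate, 1)
  structure(list(codon_summary = codon_summary, phi_summary = phi_summary,
                 chains = list(deltaM = chain_dM, deltaEta = chain_dEta,
                               phi = chain_phi),
                 acceptance = list(phi_mean_rate = mean(post_phi_rate)),
                 n_iter = n_iter, burn_in = burn_in, thin = thin),
            class = "smde_fit")
}

#' @export
print.smde_fit <- function(x, ...) {
  cat(sprintf("smde_fit: %d codon parameters, %d genes, %d kept draws\n",
              nrow(x$codon_summary), nrow(x$phi_summary),
              nrow(x$chains$deltaM)))
  invisible(x)
}
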