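# Codon-usage probability model, simulation regimes, likelihood, fitting.

code <- genetic_code()

test_that("codon probabilities are a proper softmax of the model offsets", {
  # all offsets zero -> uniform 1/n_a for any phi
  p0 <- codon_parameters(numeric(0), numeric(0), code)
  for (fam in c("N", "I", "V", "L")) {
    n_a <- length(code$families[[fam]])
    for (phi in c(0.1, 1, 5)) {
      expect_equal(unname(codon_probabilities(fam, p0, phi, code)),
                   rep(1 / n_a, n_a), tolerance = 1e-15)
    }
  }
  # 2-codon family, deltaM = ln 2 on the non-reference codon
  p1 <- codon_parameters(c(AAC = log(2)), numeric(0), code)
  pr <- codon_probabilities("N", p1, 1, code)
  expect_equal(unname(pr), c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_named(pr, c("AAC", "AAT"))
})

test_that("probabilities match a direct-formula oracle on random draws", {
  set.seed(101)
  for (rep in 1:200) {
    fam <- sample(names(code$families)[lengths(code$families) > 1], 1)
    codons <- code$families[[fam]]
    free <- setdiff(codons, code$reference[[fam]])
    dm <- setNames(rnorm(length(free)), free)
    de <- setNames(rnorm(length(free)), free)
    phi <- exp(rnorm(1))
    params <- codon_parameters(dm, de, code)
    got <- codon_probabilities(fam, params, phi, code)
    # independent direct evaluation, no stabilisation
    dm_full <- setNames(rep(0, length(codons)), codons); dm_full[free] <- dm
    de_full <- setNames(rep(0, length(codons)), codons); de_full[free] <- de
    w <- exp(-dm_full - de_full * phi)
    expect_equal(unname(got), unname(w / sum(w)), tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("shift invariance, phi limits, and monotonicity hold", {
  set.seed(11)
  fam <- "V"
  free <- setdiff(code$families[[fam]], code$reference[[fam]])
  dm <- setNames(rnorm(3), free); de <- setNames(rnorm(3), free)
  params <- codon_parameters(dm, de, code)
  p_ref <- codon_probabilities(fam, params, 2, code)
  # adding a constant to all deltaM within the family changes nothing
  shifted <- params
  shifted$deltaM[[fam]] <- params$deltaM[[fam]] + 1.7
  expect_equal(unname(codon_probabilities(fam, shifted, 2, code)),
               unname(p_ref), tolerance = 1e-12)
  # phi -> 0 collapses onto the mutation-only probabilities
  mut_only <- codon_parameters(dm, setNames(rep(0, 3), free), code)
  expect_equal(unname(codon_probabilities(fam, params, 1e-12, code)),
               unname(codon_probabilities(fam, mut_only, 1, code)),
               tolerance = 1e-9)
  # 2-codon family with positive selection offset: p decreasing in phi
  sel <- codon_parameters(numeric(0), c(AAC = 0.5), code)
  probs <- vapply(c(0.5, 1, 2, 4), function(phi)
    codon_probabilities("N", sel, phi, code)[["AAC"]], numeric(1))
  expect_true(all(diff(probs) < 0))
})

test_that("empirical mutation params follow the stationary-frequency rule", {
  # all rates equal -> uniform stationary -> all deltaM zero
  eq <- mutation_rate_table(matrix(1, 4, 4,
                                   dimnames = list(c("A","C","G","T"),
                                                   c("A","C","G","T"))))
  p_eq <- empirical_mutation_params(eq, code)
  expect_true(all(abs(unlist(p_eq$deltaM)) < 1e-12))
  expect_true(all(unlist(p_eq$deltaEta) == 0))

  # random irreducible table: stationary distribution vs eigen oracle
  set.seed(21)
  r <- matrix(rexp(16), 4, 4, dimnames = list(c("A","C","G","T"),
                                              c("A","C","G","T")))
  diag(r) <- 0
  Q <- r; diag(Q) <- -rowSums(Q)
  ev <- eigen(t(Q))
  i0 <- which.min(abs(ev$values))
  pi_oracle <- Re(ev$vectors[, i0]); pi_oracle <- pi_oracle / sum(pi_oracle)
  names(pi_oracle) <- colnames(Q)
  pp <- empirical_mutation_params(mutation_rate_table(r), code)
  # recover the implied stationary frequencies from a family of codons
  # differing at one position: deltaM(GTA vs GTT ref) = -ln(pi_A/pi_T)
  dmv <- pp$deltaM[["V"]]
  expect_equal(unname(dmv["GTA"]), -log(pi_oracle["A"] / pi_oracle["T"]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(dmv["GTC"]), -log(pi_oracle["C"] / pi_oracle["T"]),
               tolerance = 1e-10, ignore_attr = TRUE)
  # codon weight ratio 2 -> deltaM = -ln 2 (stated rule, synthetic check)
  w_ratio <- exp(-dmv["GTG"])
  expect_equal(unname(dmv["GTG"]), -log(w_ratio), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("reducible rate tables are rejected", {
  r <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"),
                                       c("A","C","G","T")))
  r["A", "C"] <- 1; r["C", "A"] <- 1; r["G", "T"] <- 1; r["T", "G"] <- 1
  expect_error(empirical_mutation_params(mutation_rate_table(r), code),
               "reducible|stationary")
})

test_that("simulation respects templates and model probabilities", {
  # single-codon family is deterministic
  model <- model_spec("UNIFORM", code = code)
  expect_identical(simulate_codons(c(g = "M"), model, seed = 1)[["g"]], "ATG")

  # translation identity on a mixed template
  tmpl <- c(gA = "MVLKPW", gB = "GGSSTT")
  sim <- simulate_codons(tmpl, model, seed = 2)
  expect_identical(unname(translate_seqs(sim, code)), unname(tmpl))

  # SMDE frequencies converge to the per-gene probabilities
  set.seed(3)
  free <- setdiff(code$families[["V"]], "GTT")
  params <- codon_parameters(setNames(rnorm(3, 0, 0.5), free),
                             setNames(rnorm(3, 0, 0.3), free), code)
  expr <- expression_profile(c(g = 1), normalize = FALSE)
  model2 <- model_spec("SMDE", parameters = params, expression = expr,
                       code = code)
  sim2 <- simulate_codons(c(g = strrep("V", 1e5)), model2, seed = 4)
  freq <- table(factor(sim2[["g"]], levels = code$families[["V"]])) / 1e5
  p <- codon_probabilities("V", params, 1, code)
  se3 <- 3 * sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(as.numeric(freq) - p) < se3))
})

test_that("SMDE simulation requires expression for every gene", {
  params <- codon_parameters(numeric(0), numeric(0), code)
  expr <- expression_profile(c(gA = 1), normalize = FALSE)
  model <- model_spec("SMDE", parameters = params, expression = expr,
                      code = code)
  expect_error(simulate_codons(c(gB = "VV"), model, seed = 1),
               "missing from expression")
})

test_that("log-likelihood matches direct formula and brute-force oracle", {
  # single gene, 2-codon family, counts (3, 1) under p = (0.75, 0.25)
  params <- codon_parameters(c(AAC = -log(3)), numeric(0), code)
  pr <- codon_probabilities("N", params, 1, code)
  expect_equal(unname(pr), c(0.75, 0.25), tolerance = 1e-12)
  seqs <- coding_sequences(list(g1 = c(rep("AAC", 3), "AAT")), code)
  cnt <- codon_counts(seqs, code)
  expr <- expression_profile(c(g1 = 1), normalize = FALSE)
  expect_equal(smde_loglikelihood(cnt, params, expr, code),
               3 * log(0.75) + 1 * log(0.25), tolerance = 1e-12)

  # random counts/params vs term-by-term summation oracle
  set.seed(31)
  seqs2 <- random_codon_seqs(6, code, min_len = 30, max_len = 80, seed = 32)
  cnt2 <- codon_counts(seqs2, code)
  dm <- de <- numeric(0)
  for (fam in names(code$families)) {
    free <- setdiff(code$families[[fam]], code$reference[[fam]])
    dm <- c(dm, setNames(rnorm(length(free), 0, 0.6), free))
    de <- c(de, setNames(rnorm(length(free), 0, 0.4), free))
  }
  params2 <- codon_parameters(dm, de, code)
  phi <- exp(rnorm(6, 0, 0.8))
  names(phi) <- rownames(cnt2)
  expr2 <- expression_profile(phi, normalize = FALSE)
  oracle <- 0
  for (g in rownames(cnt2)) {
    for (fam in names(code$families)) {
      p <- codon_probabilities(fam, params2, unname(phi[g]), code)
      for (cd in names(p)) {
        if (cnt2[g, cd] > 0) oracle <- oracle + cnt2[g, cd] * log(p[[cd]])
      }
    }
  }
  expect_equal(smde_loglikelihood(cnt2, params2, expr2, code), oracle,
               tolerance = 1e-9)
})

test_that("counts proportional to probabilities maximise the likelihood", {
  # multinomial MLE property, checked by perturbing the parameters
  params <- codon_parameters(c(AAC = log(2)), numeric(0), code)
  p <- codon_probabilities("N", params, 1, code)  # (1/3, 2/3)
  seqs <- coding_sequences(list(g1 = c(rep("AAC", 100), rep("AAT", 200))), code)
  cnt <- codon_counts(seqs, code)
  expr <- expression_profile(c(g1 = 1), normalize = FALSE)
  ll_at_mle <- smde_loglikelihood(cnt, params, expr, code)
  for (eps in c(-0.3, -0.1, 0.1, 0.3)) {
    pert <- codon_parameters(c(AAC = log(2) + eps), numeric(0), code)
    expect_lt(smde_loglikelihood(cnt, pert, expr, code), ll_at_mle)
  }
})

test_that("fit_smde recovers a mutation-only null and is label-consistent", {
  set.seed(41)
  code1 <- genetic_code()
  prot <- gen_proteome(40, mean_length = 200, seed = 42)
  params <- gen_parameters(code1, sd_deltaM = 0.5, sd_deltaEta = 0, seed = 43)
  model <- model_spec("MUTATION_ROC", parameters = params, code = code1)
  seqs <- simulate_codons(prot$proteins, model, seed = 44)
  cnt <- codon_counts(seqs, code1)
  fit <- fit_smde(cnt, code1, n_iter = 600, burn_in = 250, thin = 2, seed = 45)
  cs <- fit$codon_summary
  # data carry no selection signal: most dEta credible intervals cover 0
  covers <- cs$deltaEta_q2.5 <= 0 & cs$deltaEta_q97.5 >= 0
  expect_gte(mean(covers), 0.9)
  # deltaM point estimates track the generating values
  truth <- as.data.frame(params)
  truth <- truth[match(cs$codon, truth$codon), ]
  expect_gte(cor(cs$deltaM_mean, truth$deltaM), 0.9)
})

test_that("phi estimates are label-consistent under gene relabeling", {
  # phi is identified only when selection offsets are nonzero, so use
  # SMDE-simulated data; the same data with swapped gene ids must give
  # the same per-gene estimates up to Monte Carlo error
  code1 <- genetic_code()
  prot <- gen_proteome(40, mean_length = 250, seed = 52)
  params <- gen_parameters(code1, sd_deltaM = 0.5, sd_deltaEta = 0.4, seed = 53)
  expr <- gen_expression(40, sdlog = 1.2, seed = 54,
                         gene_ids = names(prot$proteins))
  model <- model_spec("SMDE", parameters = params, expression = expr,
                      code = code1)
  seqs <- simulate_codons(prot$proteins, model, seed = 55)
  cnt <- codon_counts(seqs, code1)
  fit <- fit_smde(cnt, code1, n_iter = 800, burn_in = 300, thin = 2, seed = 56)
  cnt_swapped <- cnt[rev(seq_len(nrow(cnt))), ]
  fit2 <- fit_smde(cnt_swapped, code1, n_iter = 800, burn_in = 300,
                   thin = 2, seed = 56)
  m1 <- fit$phi_summary$phi_mean[match(rownames(cnt), fit$phi_summary$gene_id)]
  m2 <- fit2$phi_summary$phi_mean[match(rownames(cnt), fit2$phi_summary$gene_id)]
  expect_gte(cor(m1, m2), 0.9)
})

test_that("fit_smde validates inputs", {
  seqs <- coding_sequences(list(g1 = c("GTT", "GTA")), code)
  cnt <- codon_counts(seqs, code)
  expect_error(fit_smde(cnt, code), "at least 2 genes")
  cnt2 <- rbind(cnt, g2 = cnt[1, ])
  rownames(cnt2) <- c("g1", "g2")
  expect_error(fit_smde(cnt2, code, init_scale = -1), "positive")
  # counts covering one family: every other family warns as unobserved
  w <- capture_warnings(fit_smde(cnt2, code, n_iter = 20, burn_in = 10,
                                 seed = 1))
  expect_true(length(w) > 0 && all(grepl("never observed", w)))
})
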