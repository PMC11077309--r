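# Selection-mutation-drift equilibrium (SMDE) codon-usage model.
#
# For a synonymous family with codons i = 1..N, the probability that gene g
# (with expression phi_g) uses codon i is
#
#   p_{i,g} = exp(-dM_i - dEta_i * phi_g) / sum_j exp(-dM_j - dEta_j * phi_g)
#
# where dM is the mutation-bias offset and dEta the selection offset,
# both relative to the family's reference codon (dM = dEta = 0 there).
# Special cases: dM = dEta = 0 gives the Uniform model; dEta = 0 gives a
# mutation-only model; phi -> 0 collapses SMDE onto mutation-only.

MODEL_NAMES <- c("UNIFORM", "MUTATION_ROC", "MUTATION_EMPIRICAL", "SMDE")

#' Construct per-codon mutation-bias and selection parameters
#'
#' @param deltaM named numeric vector (codon -> mutation-bias offset,
#'   natural-log scale). Must include every non-reference codon of every
#'   family it covers; reference codons may be omitted (they are fixed at
#'   0) but if present must be 0.
#' @param deltaEta named numeric vector, same layout, selection offsets
#'   per unit expression.
#' @param code a [genetic_code()] object.
#' @return object of class `codon_parameters`: list of per-family numeric
#'   vectors `deltaM[[fam]]`, `deltaEta[[fam]]`, in family codon order.
#' @export
codon_parameters <- function(deltaM, deltaEta, code = genetic_code()) {
  dm <- list(); de <- list()
  for (fam in names(code$families)) {
    codons <- code$families[[fam]]
    ref <- code$reference[[fam]]
    m <- stats::setNames(rep(0, length(codons)), codons)
    e <- m
    hit <- intersect(codons, names(deltaM))
    m[hit] <- deltaM[hit]
    hit <- intersect(codons, names(deltaEta))
    e[hit] <- deltaEta[hit]
    if (!all(is.finite(m)) || !all(is.finite(e))) {
      stop("non-finite parameter in family ", fam, call. = FALSE)
    }
    if (m[ref] != 0 || e[ref] != 0) {
      stop("reference codon ", ref, " must have deltaM = deltaEta = 0",
           call. = FALSE)
    }
    dm[[fam]] <- m; de[[fam]] <- e
  }
  structure(list(deltaM = dm, deltaEta = de, code = code),
            class = "codon_parameters")
}

#' @export
print.codon_parameters <- function(x, ...) {
  cat("codon_parameters over", length(x$deltaM), "families\n")
  invisible(x)
}

# Flatten codon_parameters to a data.frame (family, codon, deltaM, deltaEta).
#' Tabulate codon parameters
#' @param params a `codon_parameters` object.
#' @return data.frame with columns family, codon, deltaM, deltaEta.
#' @export
as.data.frame.codon_parameters <- function(x, ...) {
  do.call(rbind, lapply(names(x$deltaM), function(fam) {
    data.frame(family = fam, codon = names(x$deltaM[[fam]]),
               deltaM = unname(x$deltaM[[fam]]),
               deltaEta = unname(x$deltaEta[[fam]]),
               row.names = NULL)
  }))
}

#' Construct a per-gene expression profile
#'
#' Expression values phi scale the strength of selection on codon usage.
#' They are normalised to geometric mean 1, the package's identifiability
#' convention (the model is invariant to rescaling phi if dEta is
#' rescaled inversely).
#'
#' @param phi named positive numeric vector (gene_id -> expression).
#' @param normalize logical; normalise to geometric mean 1 (default TRUE).
#' @return object of class `expression_profile` (a named numeric vector).
#' @export
expression_profile <- function(phi, normalize = TRUE) {
  if (is.null(names(phi)) || anyDuplicated(names(phi))) {
    stop("phi must be named by unique gene_id", call. = FALSE)
  }
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("all phi must be positive and finite", call. = FALSE)
  }
  if (normalize) phi <- phi / geom_mean(phi)
  structure(phi, class = "expression_profile")
}

#' Construct a 4x4 single-nucleotide mutation-rate table
#'
#' @param rate 4x4 nonnegative matrix with dimnames over A,C,G,T
#'   (diagonal ignored). Every base must have at least one positive
#'   outgoing rate.
#' @return object of class `mutation_rate_table`.
#' @export
mutation_rate_table <- function(rate) {
  bases <- c("A", "C", "G", "T")
  rate <- as.matrix(rate)
  if (!identical(dim(rate), c(4L, 4L))) stop("rate must be 4x4", call. = FALSE)
  if (is.null(dimnames(rate))) dimnames(rate) <- list(bases, bases)
  rate <- rate[bases, bases]
  if (any(rate[row(rate) != col(rate)] < 0)) {
    stop("rates must be nonnegative", call. = FALSE)
  }
  diag(rate) <- 0
  if (any(rowSums(rate) == 0)) {
    stop("every base needs at least one positive outgoing rate", call. = FALSE)
  }
  structure(rate, class = "mutation_rate_table")
}

#' Bundle a codon-usage model specification
#'
#' @param name one of `"UNIFORM"`, `"MUTATION_ROC"`, `"MUTATION_EMPIRICAL"`,
#'   `"SMDE"`.
#' @param parameters `codon_parameters` (required for MUTATION_ROC and
#'   SMDE; derived from `mutation_rates` for MUTATION_EMPIRICAL).
#' @param expression `expression_profile` (SMDE only).
#' @param mutation_rates `mutation_rate_table` (MUTATION_EMPIRICAL only).
#' @param code a [genetic_code()] object.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, parameters = NULL, expression = NULL,
                       mutation_rates = NULL, code = genetic_code()) {
  name <- match.arg(name, MODEL_NAMES)
  if (name == "MUTATION_EMPIRICAL") {
    if (is.null(mutation_rates)) stop("MUTATION_EMPIRICAL needs mutation_rates",
                                      call. = FALSE)
    parameters <- empirical_mutation_params(mutation_rates, code)
  }
  if (name %in% c("MUTATION_ROC", "SMDE") && is.null(parameters)) {
    stop(name, " needs codon parameters", call. = FALSE)
  }
  if (name == "SMDE" && is.null(expression)) {
    stop("SMDE needs an expression profile", call. = FALSE)
  }
  structure(list(name = name, parameters = parameters,
                 expression = expression, mutation_rates = mutation_rates,
                 code = code), class = "model_spec")
}

#' Synonymous-codon probabilities for one family (Eq. of the SMDE model)
#'
#' Evaluates `p_i = exp(-dM_i - dEta_i * phi) / sum_j exp(...)` over the
#' codons of one family, with a stabilised softmax.
#'
#' @param family family label (e.g. `"V"`).
#' @param params a `codon_parameters` object.
#' @param phi positive scalar gene expression (ignored when all
#'   `deltaEta` are 0).
#' @param code a [genetic_code()] object.
#' @return named probability vector over the family's codons (sums to 1).
#' @export
codon_probabilities <- function(family, params, phi = 1, code = genetic_code()) {
  dm <- params$deltaM[[family]]
  de <- params$deltaEta[[family]]
  if (is.null(dm)) stop("unknown family: ", family, call. = FALSE)
  if (!is.finite(phi) || phi <= 0) stop("phi must be positive and finite",
                                        call. = FALSE)
  .softmax_probs(dm, de, phi)
}

.softmax_probs <- function(dm, de, phi) {
  x <- -(dm + de * phi)
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# Probabilities for one family under a model_spec, for gene g.
.model_family_probs <- function(model, family, gene_id = NULL) {
  codons <- model$code$families[[family]]
  switch(model$name,
    UNIFORM = stats::setNames(rep(1 / length(codons), length(codons)), codons),
    MUTATION_ROC = ,
    MUTATION_EMPIRICAL = .softmax_probs(model$parameters$deltaM[[family]],
                                        rep(0, length(codons)), 1),
    SMDE = {
      phi <- model$expression[gene_id]
      if (is.na(phi)) stop("gene '", gene_id, "' missing from expression profile",
                           call. = FALSE)
      .softmax_probs(model$parameters$deltaM[[family]],
                     model$parameters$deltaEta[[family]], unname(phi))
    })
}

#' Convert empirical nucleotide mutation rates to mutation-bias offsets
#'
#' Computes the stationary base frequencies of the single-nucleotide rate
#' matrix, gives each codon the stationary weight
#' `w = pi[b1] * pi[b2] * pi[b3]` (independent sites), and sets, within
#' each family, `deltaM_i = -log(w_i / w_ref)` with all `deltaEta = 0`.
#'
#' @param rates a [mutation_rate_table()].
#' @param code a [genetic_code()] object.
#' @return `codon_parameters` with all selection offsets 0.
#' @export
empirical_mutation_params <- function(rates, code = genetic_code()) {
  if (!inherits(rates, "mutation_rate_table")) rates <- mutation_rate_table(rates)
  Q <- unclass(rates)
  diag(Q) <- -rowSums(Q)
  # stationary distribution: pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, 4))
  pi_hat <- tryCatch(qr.solve(A, c(0, 0, 0, 0, 1)),
                     error = function(e) stop("rate matrix has no unique stationary distribution",
                                              call. = FALSE))
  if (any(pi_hat <= 1e-12)) {
    stop("rate matrix is reducible: stationary distribution not strictly positive",
         call. = FALSE)
  }
  pi_hat <- stats::setNames(pi_hat / sum(pi_hat), colnames(Q))
  sense <- SENSE_CODONS(code)
  w <- vapply(sense, function(cd) {
    b <- strsplit(cd, "")[[1]]
    pi_hat[b[1]] * pi_hat[b[2]] * pi_hat[b[3]]
  }, numeric(1))
  dm <- numeric(0)
  for (fam in names(code$families)) {
    codons <- code$families[[fam]]
    ref <- code$reference[[fam]]
    dm <- c(dm, stats::setNames(-log(w[codons] / w[ref]), codons))
  }
  codon_parameters(deltaM = dm, deltaEta = stats::setNames(numeric(0), character(0)),
                   code = code)
}

#' Simulate synonymous codon usage for protein templates
#'
#' For each occurrence of an amino acid in each template, a synonymous
#' codon is drawn from the model's multinomial probabilities (per-gene
#' probabilities under SMDE). Each gene uses its own deterministic
#' sub-stream of the top-level seed, so results are reproducible and
#' independent of gene order.
#'
#' @param templates named character vector of amino acid strings (or the
#'   `proteins` element of [gen_proteome()]).
#' @param model a [model_spec()].
#' @param seed integer seed.
#' @return a `codon_seqs` object translating back to `templates`.
#' @export
simulate_codons <- function(templates, model, seed) {
  code <- model$code
  ids <- names(templates)
  if (is.null(ids)) stop("templates must be named by gene_id", call. = FALSE)
  if (model$name == "SMDE") {
    missing_phi <- setdiff(ids, names(model$expression))
    if (length(missing_phi)) {
      stop("gene '", missing_phi[1L], "' missing from expression profile",
           call. = FALSE)
    }
  }
  seeds <- derive_seeds(seed, length(ids))
  out <- vector("list", length(ids))
  names(out) <- ids
  for (k in seq_along(ids)) {
    g <- ids[k]
    set.seed(seeds[k])
    aa <- strsplit(templates[[g]], "")[[1]]
    codons <- character(length(aa))
    # assign per family; serine may map to two families when split
    for (fam in names(code$families)) {
      codons_fam <- code$families[[fam]]
      fam_aa <- code$table[[codons_fam[1]]]
      pos <- which(aa == fam_aa)
      if (fam_aa == "S" && code$split_serine) {
        # split sites between the two serine families uniformly
        if (fam == "S") {
          sel <- pos[stats::runif(length(pos)) < 2 / 3]  # 4 of 6 codons
          attr(codons, "ser_tc") <- sel
          pos <- sel
        } else {
          pos <- setdiff(pos, attr(codons, "ser_tc"))
        }
      }
      if (!length(pos)) next
      p <- .model_family_probs(model, fam, g)
      codons[pos] <- codons_fam[sample.int(length(codons_fam), length(pos),
                                           replace = TRUE, prob = p)]
    }
    attr(codons, "ser_tc") <- NULL
    bad <- which(codons == "")
    if (length(bad)) {
      stop("no synonymous family for amino acid '", aa[bad[1L]],
           "' in gene '", g, "'", call. = FALSE)
    }
    out[[k]] <- codons
  }
  structure(out, class = "codon_seqs")
}

#' Multinomial log-likelihood of codon counts under the SMDE model
#'
#' `sum_g sum_fam sum_i count * log p_{i,g}` with per-gene family
#' probabilities from the SMDE formula. A structurally zero probability
#' facing a positive count returns `-Inf` with a warning.
#'
#' @param counts genes x 61 sense-codon count matrix (from
#'   [codon_counts()]).
#' @param params `codon_parameters`.
#' @param expr `expression_profile` covering the count matrix's genes.
#' @param code a [genetic_code()] object.
#' @return scalar log-likelihood.
#' @export
smde_loglikelihood <- function(counts, params, expr, code = genetic_code()) {
  phi <- unclass(expr)[rownames(counts)]
  if (anyNA(phi)) stop("expression profile missing genes", call. = FALSE)
  ll <- 0
  for (fam in names(code$families)) {
    codons <- code$families[[fam]]
    if (length(codons) < 1L) next
    C <- counts[, codons, drop = FALSE]
    A <- -outer(unname(phi), params$deltaEta[[fam]])
    A <- sweep(A, 2, params$deltaM[[fam]])  # A[g,i] = -dM_i - dEta_i*phi_g
    m <- A[cbind(seq_len(nrow(A)), max.col(A, "first"))]
    logZ <- log(rowSums(exp(A - m))) + m
    logp <- A - logZ
    if (any(!is.finite(logp) & C > 0)) {
      warning("zero-probability codon with positive count; log-likelihood is -Inf")
      return(-Inf)
    }
    ll <- ll + sum(C * logp)
  }
  ll
}
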