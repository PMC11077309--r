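# Synthetic-study generator: proteomes with secondary-structure labels,
# log-normal gene expression, codon parameters, codon usage under any of
# the four models, and per-site dihedral angles drawn from per-(aa, ss)
# torus mixtures that are codon-independent under the null. Optional
# injected codon-specific psi shifts provide known positives for power
# studies.

# Default amino-acid frequencies, loosely matching a bacterial proteome
# (relative usage; normalised in gen_proteome). The spread in usage is
# deliberate: rare residues give small per-stratum sample sizes, so the
# noise level of the angle test varies across amino acids the way it
# does in real structural data.
DEFAULT_AA_FREQ <- c(
  A = 9.5, R = 5.5, N = 3.9, D = 5.4, C = 1.2, Q = 4.4, E = 5.8,
  G = 7.4, H = 2.3, I = 6.0, L = 10.7, K = 4.4, M = 2.8, F = 3.9,
  P = 4.4, S = 5.8, T = 5.4, W = 1.5, Y = 2.8, V = 7.1)

DEFAULT_SS_PROBS <- c(HELIX = 0.35, SHEET = 0.25, TURN = 0.20, OTHER = 0.20)

#' Default per-(aa, ss) torus angle model
#'
#' Every (amino acid, secondary structure) cell is a two-component
#' mixture of independent-axis wrapped normals: an alpha basin near
#' (-63, -43) and a beta basin near (-120, 135), with class-dependent
#' weights (helices mostly alpha, sheets mostly beta). Per-amino-acid
#' scale factors widen or narrow the basins (glycine broad, proline
#' narrow), emulating residue-specific Ramachandran variability.
#'
#' @param code a [genetic_code()] object (amino-acid universe).
#' @return nested list: `model[[aa]][[ss]]` is a list with `means`
#'   (2 x 2 matrix, rows = components, cols = (phi, psi)), `sds`
#'   (2 x 2), `weights` (length 2).
#' @export
default_angle_model <- function(code = genetic_code()) {
  aas <- sort(unique(code$table[SENSE_CODONS(code)]))
  w_ss <- list(HELIX = c(0.85, 0.15), SHEET = c(0.12, 0.88),
               TURN = c(0.45, 0.55), OTHER = c(0.50, 0.50))
  base_means <- rbind(alpha = c(-63, -43), beta = c(-120, 135))
  base_sds <- rbind(alpha = c(11, 11), beta = c(16, 16))
  # residue-specific spread: glycine broad, proline narrow, the rest
  # graded deterministically across the alphabet
  scale_aa <- stats::setNames(0.8 + 0.6 * (seq_along(aas) - 1) / (length(aas) - 1),
                              aas)
  scale_aa["G"] <- 2.0
  scale_aa["P"] <- 0.6
  out <- list()
  for (aa in aas) {
    per_ss <- list()
    for (ss in SS_CLASSES) {
      per_ss[[ss]] <- list(means = base_means,
                           sds = base_sds * scale_aa[[aa]],
                           weights = w_ss[[ss]])
    }
    out[[aa]] <- per_ss
  }
  out
}

#' Generate a log-normal gene-expression profile
#'
#' `log(phi) ~ Normal(0, sdlog^2)`, then normalised to geometric mean 1.
#'
#' @param n_genes number of genes (>= 1).
#' @param sdlog standard deviation of log expression (>= 0).
#' @param seed integer seed.
#' @param gene_ids optional gene ids (default `g1..gN`).
#' @return an [expression_profile()].
#' @export
gen_expression <- function(n_genes, sdlog = 1, seed = 1, gene_ids = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (sdlog < 0) stop("sdlog must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  phi <- exp(stats::rnorm(n_genes, 0, sdlog))
  names(phi) <- gene_ids %||% paste0("g", seq_len(n_genes))
  expression_profile(phi, normalize = TRUE)
}

#' Generate random codon parameters
#'
#' Non-reference codons draw `deltaM ~ Normal(0, sd_deltaM^2)` and
#' `deltaEta ~ Normal(0, sd_deltaEta^2)`; reference codons stay 0.
#'
#' @param code a [genetic_code()] object.
#' @param sd_deltaM,sd_deltaEta draw scales (>= 0).
#' @param seed integer seed.
#' @return a [codon_parameters()] object.
#' @export
gen_parameters <- function(code = genetic_code(), sd_deltaM = 0.5,
                           sd_deltaEta = 0.3, seed = 1) {
  if (sd_deltaM < 0 || sd_deltaEta < 0) stop("sds must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  dm <- numeric(0); de <- numeric(0)
  for (fam in names(code$families)) {
    codons <- setdiff(code$families[[fam]], code$reference[[fam]])
    if (!length(codons)) next
    dm <- c(dm, stats::setNames(stats::rnorm(length(codons), 0, sd_deltaM), codons))
    de <- c(de, stats::setNames(stats::rnorm(length(codons), 0, sd_deltaEta), codons))
  }
  codon_parameters(dm, de, code)
}

#' Generate a synthetic proteome with secondary-structure labels
#'
#' Gene lengths are geometric with the given mean above a floor of
#' `min_length`; amino acids are i.i.d. from `aa_frequencies`;
#' per-site secondary-structure labels are drawn from `ss_probs`
#' (optionally a per-amino-acid matrix).
#'
#' @param n_genes number of genes.
#' @param mean_length mean protein length in amino acids.
#' @param min_length minimum length (default 30).
#' @param aa_frequencies named 20-vector of relative amino-acid usage.
#' @param ss_probs named 4-vector over HELIX/SHEET/TURN/OTHER, or a
#'   20 x 4 matrix (rows = amino acids) of per-aa class probabilities.
#' @param seed integer seed.
#' @return list with `proteins` (named character vector) and `ss`
#'   (named list of per-site class labels).
#' @export
gen_proteome <- function(n_genes = 100, mean_length = 300, min_length = 30,
                         aa_frequencies = DEFAULT_AA_FREQ,
                         ss_probs = DEFAULT_SS_PROBS, seed = 1) {
  if (any(aa_frequencies < 0) || sum(aa_frequencies > 0) < 1) {
    stop("degenerate amino-acid frequency vector", call. = FALSE)
  }
  if (mean_length <= min_length) stop("mean_length must exceed min_length",
                                      call. = FALSE)
  set.seed(as.integer(seed))
  aa_frequencies <- aa_frequencies / sum(aa_frequencies)
  aas <- names(aa_frequencies)
  lens <- min_length + stats::rgeom(n_genes, 1 / (mean_length - min_length + 1))
  ids <- paste0("g", seq_len(n_genes))
  proteins <- character(n_genes); names(proteins) <- ids
  ss <- vector("list", n_genes); names(ss) <- ids
  ss_mat <- if (is.matrix(ss_probs)) ss_probs else
    matrix(rep(ss_probs, each = length(aas)), nrow = length(aas),
           dimnames = list(aas, names(ss_probs)))
  ss_mat <- ss_mat / rowSums(ss_mat)
  for (k in seq_len(n_genes)) {
    aa <- sample(aas, lens[k], replace = TRUE, prob = aa_frequencies)
    proteins[k] <- paste(aa, collapse = "")
    lab <- character(lens[k])
    for (a in unique(aa)) {
      i <- which(aa == a)
      lab[i] <- sample(colnames(ss_mat), length(i), replace = TRUE,
                       prob = ss_mat[a, ])
    }
    ss[[k]] <- lab
  }
  list(proteins = proteins, ss = ss)
}

#' Draw dihedral angles for a record template
#'
#' Under the null, each record's (phi, psi) is drawn from its
#' (amino acid, secondary structure) mixture regardless of codon. With
#' `effect_injection = list(codon=, psi_shift=, fraction=)`, a random
#' fraction of the records carrying the target codon get their psi
#' wrapped-shifted by `psi_shift` degrees, providing known-positive
#' pairs for power studies. Injected rows are flagged in the attribute
#' `"injected"`.
#'
#' @param template data.frame with columns `gene_id, position, aa, codon,
#'   ss` (e.g. a record table without angles).
#' @param angle_model output of [default_angle_model()] (or same shape).
#' @param effect_injection optional list (`codon`, `psi_shift` in
#'   (-180, 180], `fraction` in (0, 1], default 1).
#' @param seed integer seed.
#' @return dihedral-record data.frame with `phi_deg`, `psi_deg` in
#'   `[-180, 180)` and attribute `injected` (integer row indices).
#' @export
gen_angles <- function(template, angle_model = default_angle_model(),
                       effect_injection = NULL, seed = 1) {
  set.seed(as.integer(seed))
  n <- nrow(template)
  phi <- numeric(n); psi <- numeric(n)
  grp <- interaction(template$aa, template$ss, drop = TRUE)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    aa <- template$aa[rows[1]]; ss <- template$ss[rows[1]]
    comp <- angle_model[[aa]][[ss]]
    if (is.null(comp)) stop("angle model missing (", aa, ", ", ss, ")",
                            call. = FALSE)
    z <- sample.int(length(comp$weights), length(rows), replace = TRUE,
                    prob = comp$weights)
    phi[rows] <- rwrapnorm(length(rows), comp$means[z, 1], comp$sds[z, 1])
    psi[rows] <- rwrapnorm(length(rows), comp$means[z, 2], comp$sds[z, 2])
  }
  injected <- integer(0)
  if (!is.null(effect_injection)) {
    shift <- effect_injection$psi_shift
    if (shift <= -180 || shift > 180) stop("psi_shift must be in (-180, 180]",
                                           call. = FALSE)
    frac <- effect_injection$fraction %||% 1
    hits <- which(template$codon == effect_injection$codon)
    injected <- sort(sample(hits, round(frac * length(hits))))
    psi[injected] <- wrap_degrees(psi[injected] + shift)
  }
  out <- data.frame(gene_id = template$gene_id, position = template$position,
                    aa = template$aa, codon = template$codon,
                    ss = template$ss, phi_deg = phi, psi_deg = psi)
  attr(out, "injected") <- injected
  out
}

#' Assemble a synthetic-study configuration
#'
#' @param n_genes,mean_length,min_length proteome size controls.
#' @param sdlog_phi log-sd of gene expression.
#' @param sd_deltaM,sd_deltaEta codon-parameter draw scales.
#' @param model codon-usage model name (see [model_spec()]).
#' @param aa_frequencies,ss_probs,angle_model see [gen_proteome()] and
#'   [gen_angles()].
#' @param mutation_rates [mutation_rate_table()] (MUTATION_EMPIRICAL only).
#' @param effect_injection optional injection spec (see [gen_angles()]).
#' @param split_serine passed to [genetic_code()].
#' @param seed top-level seed; all stages derive sub-streams from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 150, mean_length = 300,
                             min_length = 30, sdlog_phi = 1,
                             sd_deltaM = 0.5, sd_deltaEta = 0.3,
                             model = "SMDE",
                             aa_frequencies = DEFAULT_AA_FREQ,
                             ss_probs = DEFAULT_SS_PROBS,
                             angle_model = NULL,
                             mutation_rates = NULL,
                             effect_injection = NULL,
                             split_serine = FALSE, seed = 1) {
  model <- match.arg(model, MODEL_NAMES)
  structure(list(n_genes = n_genes, mean_length = mean_length,
                 min_length = min_length, sdlog_phi = sdlog_phi,
                 sd_deltaM = sd_deltaM, sd_deltaEta = sd_deltaEta,
                 model = model, aa_frequencies = aa_frequencies,
                 ss_probs = ss_probs, angle_model = angle_model,
                 mutation_rates = mutation_rates,
                 effect_injection = effect_injection,
                 split_serine = split_serine, seed = seed),
            class = "synthetic_config")
}

#' Generate a complete synthetic study
#'
#' Composes [gen_proteome()], [gen_expression()], [gen_parameters()],
#' [simulate_codons()] and [gen_angles()] into one consistent study:
#' sequences translating to the generated proteome, per-site dihedral
#' records, the generating truth, and (optionally) injected
#' codon-specific angle effects.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_study`: list with `sequences`,
#'   `expression`, `parameters`, `records`, `model` (a [model_spec()]),
#'   `proteome`, `code`, and `truth` (injection bookkeeping).
#' @export
make_study <- function(config = synthetic_config()) {
  code <- genetic_code(split_serine = config$split_serine)
  seeds <- derive_seeds(config$seed, 5)
  prot <- gen_proteome(config$n_genes, config$mean_length, config$min_length,
                       config$aa_frequencies, config$ss_probs, seed = seeds[1])
  expr <- gen_expression(config$n_genes, config$sdlog_phi, seed = seeds[2],
                         gene_ids = names(prot$proteins))
  params <- gen_parameters(code, config$sd_deltaM, config$sd_deltaEta,
                           seed = seeds[3])
  model <- switch(config$model,
    UNIFORM = model_spec("UNIFORM", code = code),
    MUTATION_ROC = {
      p <- params
      for (fam in names(p$deltaEta)) p$deltaEta[[fam]][] <- 0
      model_spec("MUTATION_ROC", parameters = p, code = code)
    },
    MUTATION_EMPIRICAL = model_spec("MUTATION_EMPIRICAL",
                                    mutation_rates = config$mutation_rates %||%
                                      default_mutation_rates(),
                                    code = code),
    SMDE = model_spec("SMDE", parameters = params, expression = expr,
                      code = code))
  seqs <- simulate_codons(prot$proteins, model, seed = seeds[4])
  template <- do.call(rbind, lapply(names(seqs), function(g) {
    codons <- seqs[[g]]
    data.frame(gene_id = g, position = seq_along(codons) - 1L,
               aa = unname(code$table[codons]), codon = codons,
               ss = prot$ss[[g]])
  }))
  rownames(template) <- NULL
  am <- config$angle_model %||% default_angle_model(code)
  records <- gen_angles(template, am, config$effect_injection, seed = seeds[5])
  truth <- list(effect_injection = config$effect_injection,
                injected_rows = attr(records, "injected"))
  if (!is.null(config$effect_injection)) {
    tc <- config$effect_injection$codon
    fam <- code$family_of[[tc]]
    others <- setdiff(code$families[[fam]], tc)
    truth$affected_pairs <- data.frame(
      aa = fam,
      codon_a = pmin(tc, others),
      codon_b = pmax(tc, others), row.names = NULL)
  }
  structure(list(sequences = seqs, expression = expr, parameters = params,
                 records = records, model = model, proteome = prot,
                 code = code, truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d genes, %d residue records, model %s\n",
              length(x$sequences), nrow(x$records), x$model$name))
  invisible(x)
}

#' Default single-nucleotide mutation-rate table
#'
#' A transition-biased, AT-biased rate table of the shape reported by
#' mutation-accumulation experiments in enteric bacteria; used as the
#' stand-in input for the mutation-empirical model when no measured table
#' is supplied. Units are arbitrary (only ratios matter).
#'
#' @return a [mutation_rate_table()].
#' @export
default_mutation_rates <- function() {
  bases <- c("A", "C", "G", "T")
  r <- matrix(1, 4, 4, dimnames = list(bases, bases))
  # transitions faster than transversions; G/C -> A/T faster than reverse
  r["A", "G"] <- 2.0; r["G", "A"] <- 4.0
  r["C", "T"] <- 4.0; r["T", "C"] <- 2.0
  r["G", "T"] <- 1.5; r["C", "A"] <- 1.5
  r["A", "C"] <- 0.8; r["T", "G"] <- 0.8
  r["A", "T"] <- 1.0; r["T", "A"] <- 1.0
  r["G", "C"] <- 0.7; r["C", "G"] <- 0.7
  diag(r) <- 0
  mutation_rate_table(r)
}
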