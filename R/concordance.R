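# Concordance metrics between two analysis runs (e.g. an observed-style
# run and a run on null-resimulated sequences): rank correlations of the
# distance statistic and p-values over shared codon pairs, overlap of
# significant pairs, per-amino-acid positional codon agreement, and the
# noise-vs-signal diagnostic (self-distance against between-codon
# distance).

#' Wrap a results table as a labelled analysis run
#'
#' @param results results data.frame from [run_all_pairs()].
#' @param label short run label.
#' @param source_model model name that generated the sequences, or
#'   `"observed"`.
#' @return object of class `analysis_run`.
#' @export
analysis_run <- function(results, label, source_model = "observed") {
  need <- c("aa", "ss", "codon_a", "codon_b", "ddist", "p_value",
            "significant", "tested")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  key <- paste(results$aa, results$ss, results$codon_a, results$codon_b)
  if (anyDuplicated(key)) stop("duplicate (aa, ss, pair) keys", call. = FALSE)
  structure(list(results = results, label = label,
                 source_model = source_model), class = "analysis_run")
}

.run_results <- function(x) {
  if (inherits(x, "analysis_run")) x$results else x
}

.pair_key <- function(df) paste(df$aa, df$ss, df$codon_a, df$codon_b, sep = "|")

# Merge two runs on tested shared keys.
.shared_tested <- function(a, b) {
  ra <- .run_results(a); rb <- .run_results(b)
  ra <- ra[ra$tested, , drop = FALSE]
  rb <- rb[rb$tested, , drop = FALSE]
  ka <- .pair_key(ra); kb <- .pair_key(rb)
  shared <- intersect(ka, kb)
  list(a = ra[match(shared, ka), , drop = FALSE],
       b = rb[match(shared, kb), , drop = FALSE])
}

#' Spearman concordance of test statistics and p-values between two runs
#'
#' Rank correlation (average-rank ties) over the (aa, ss, codon pair)
#' keys tested in both runs, separately for the distance statistic and
#' the permutation p-value.
#'
#' @param a,b results data.frames from [run_all_pairs()] (or
#'   [analysis_run()] objects).
#' @return list with `spearman_ddist`, `spearman_pvalue`, `n_shared`.
#' @export
spearman_concordance <- function(a, b) {
  sh <- .shared_tested(a, b)
  if (nrow(sh$a) < 3L) stop("fewer than 3 shared tested pairs", call. = FALSE)
  list(spearman_ddist = stats::cor(sh$a$ddist, sh$b$ddist, method = "spearman"),
       spearman_pvalue = stats::cor(sh$a$p_value, sh$b$p_value,
                                    method = "spearman"),
       n_shared = nrow(sh$a))
}

#' Overlap of significant codon pairs between two runs
#'
#' Counts significant pairs in each run over the shared tested keys, the
#' intersection, and the pairs significant only in run `b`, with a
#' per-secondary-structure breakdown. The overlap percentage is reported
#' relative to the number significant in run `a` (the "observed" run).
#'
#' @param a,b results data.frames (or [analysis_run()] objects) carrying
#'   `significant` flags at the same alpha.
#' @return list with `n_sig_a`, `n_sig_b`, `n_sig_both`, `n_sig_only_b`,
#'   `pct_both_of_a`, and `per_ss` data.frame breakdown.
#' @export
significance_overlap <- function(a, b) {
  ra <- .run_results(a); rb <- .run_results(b)
  ka <- .pair_key(ra[ra$tested, ]); kb <- .pair_key(rb[rb$tested, ])
  if (!setequal(ka, kb)) {
    warning("tested key universes differ; restricting to intersection")
  }
  sh <- .shared_tested(a, b)
  sig_a <- sh$a$significant
  sig_b <- sh$b$significant
  per_ss <- do.call(rbind, lapply(SS_CLASSES, function(ss) {
    i <- sh$a$ss == ss
    data.frame(ss = ss,
               n_sig_a = sum(sig_a[i]),
               n_sig_b = sum(sig_b[i]),
               n_sig_both = sum(sig_a[i] & sig_b[i]),
               n_sig_only_b = sum(!sig_a[i] & sig_b[i]))
  }))
  n_sig_a <- sum(sig_a)
  n_both <- sum(sig_a & sig_b)
  list(n_sig_a = n_sig_a,
       n_sig_b = sum(sig_b),
       n_sig_both = n_both,
       n_sig_only_b = sum(!sig_a & sig_b),
       pct_both_of_a = if (n_sig_a > 0) round(100 * n_both / n_sig_a, 1) else NA_real_,
       per_ss = per_ss)
}

#' Per-amino-acid positional codon agreement between two sequence sets
#'
#' For two sets of coding sequences with identical proteins, the
#' percentage of sites of each amino acid carrying the identical codon at
#' the same position, with the uniform-usage reference value `100 / n_a`
#' attached (`n_a` = family size). For independent draws with per-site
#' codon probabilities p and q the expected agreement is
#' `100 * sum(p_i * q_i)`.
#'
#' @param seqs_a,seqs_b `codon_seqs` objects over the same genes and
#'   proteins.
#' @param code a [genetic_code()] object.
#' @return data.frame `aa, n_sites, agreement_pct,
#'   random_expectation_pct` (one row per multi-codon family; percentages
#'   to one decimal).
#' @export
positional_agreement <- function(seqs_a, seqs_b, code = genetic_code()) {
  ids <- names(seqs_a)
  if (!setequal(ids, names(seqs_b))) stop("gene sets differ", call. = FALSE)
  match_ct <- total_ct <- stats::setNames(numeric(length(code$families)),
                                          names(code$families))
  for (g in ids) {
    ca <- seqs_a[[g]]; cb <- seqs_b[[g]]
    if (length(ca) != length(cb)) {
      stop("gene '", g, "': sequence lengths differ", call. = FALSE)
    }
    fa <- code$table[ca]; fb <- code$table[cb]
    bad <- which(fa != fb)
    if (length(bad)) {
      stop(sprintf("gene '%s' position %d: translations differ (%s vs %s)",
                   g, bad[1L] - 1L, fa[bad[1L]], fb[bad[1L]]), call. = FALSE)
    }
    fam <- code$family_of[ca]
    agree <- ca == cb
    t1 <- tapply(rep(1, length(fam)), fam, sum)
    t2 <- tapply(agree, fam, sum)
    total_ct[names(t1)] <- total_ct[names(t1)] + t1
    match_ct[names(t2)] <- match_ct[names(t2)] + t2
  }
  keep <- lengths(code$families) >= 2L & total_ct > 0
  fams <- names(code$families)[keep]
  data.frame(aa = fams,
             n_sites = unname(total_ct[fams]),
             agreement_pct = round(100 * unname(match_ct[fams] / total_ct[fams]), 1),
             random_expectation_pct = round(100 / lengths(code$families)[fams], 1),
             row.names = NULL)
}

#' Correlation between self-comparison noise and between-codon signal
#'
#' For each secondary-structure class, the Spearman correlation across
#' amino acids between the mean self-distance (noise baseline, from
#' [self_distance_table()]) and the mean between-codon distance (from
#' [run_all_pairs()] results). A positive correlation indicates the
#' between-codon statistic tracks stratum noise rather than codon signal.
#'
#' @param self_stats data.frame with columns `aa, ss, mean_self_dist`
#'   (extra columns ignored; codon-level rows are averaged per (aa, ss)).
#' @param between_stats results data.frame with `aa, ss, ddist` (pair
#'   rows averaged per (aa, ss)).
#' @return data.frame `ss, n_aa, spearman, p_value` (correlation `NA`
#'   with a warning for degenerate/constant input).
#' @export
noise_signal_correlation <- function(self_stats, between_stats) {
  self_stats <- self_stats[!is.na(self_stats$mean_self_dist), , drop = FALSE]
  between_stats <- between_stats[!is.na(between_stats$ddist), , drop = FALSE]
  s_mean <- stats::aggregate(mean_self_dist ~ aa + ss, self_stats, mean)
  b_mean <- stats::aggregate(ddist ~ aa + ss, between_stats, mean)
  m <- merge(s_mean, b_mean, by = c("aa", "ss"))
  out <- lapply(SS_CLASSES, function(ss) {
    sub <- m[m$ss == ss, , drop = FALSE]
    if (nrow(sub) < 3L) {
      stop("fewer than 3 amino acids in class ", ss, call. = FALSE)
    }
    if (stats::sd(sub$mean_self_dist) == 0 || stats::sd(sub$ddist) == 0) {
      warning("constant distance vector in class ", ss,
              "; correlation undefined")
      return(data.frame(ss = ss, n_aa = nrow(sub), spearman = NA_real_,
                        p_value = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(sub$mean_self_dist, sub$ddist,
                                           method = "spearman"))
    data.frame(ss = ss, n_aa = nrow(sub), spearman = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, out)
}

#' Relabel dihedral records with codons from re-simulated sequences
#'
#' Reproduces the audit's central manipulation: keep every structural
#' observation (gene, position, amino acid, secondary structure, angles)
#' but replace the codon at each site with the codon of a re-simulated
#' sequence set. Any codon-angle association present in the original
#' records is destroyed up to chance codon agreement.
#'
#' @param records dihedral-record data.frame.
#' @param seqs `codon_seqs` with the new codons (same genes; identical
#'   proteins at the recorded positions).
#' @param code a [genetic_code()] object.
#' @return records with the `codon` column replaced.
#' @export
relabel_codons <- function(records, seqs, code = genetic_code()) {
  new_codon <- character(nrow(records))
  for (g in unique(records$gene_id)) {
    rows <- which(records$gene_id == g)
    s <- seqs[[g]]
    if (is.null(s)) stop("gene '", g, "' missing from sequences", call. = FALSE)
    pos <- records$position[rows] + 1L
    if (any(pos > length(s))) {
      stop("gene '", g, "': record position beyond sequence end", call. = FALSE)
    }
    new_codon[rows] <- s[pos]
  }
  new_aa <- code$table[new_codon]
  bad <- which(new_aa != records$aa)
  if (length(bad)) {
    stop(sprintf("gene '%s' position %d: new codon encodes %s, record has %s",
                 records$gene_id[bad[1L]], records$position[bad[1L]],
                 new_aa[bad[1L]], records$aa[bad[1L]]), call. = FALSE)
  }
  records$codon <- new_codon
  records
}
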