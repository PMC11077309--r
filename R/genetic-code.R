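# Genetic-code tables and synonymous-family bookkeeping.
#
# The standard (NCBI table 1) code is the only one supported. Families of
# synonymous codons are kept sorted lexicographically and each family
# designates its lexicographically last codon as the reference codon: the
# codon whose mutation-bias and selection offsets are pinned to zero. Any
# fixed convention works because the codon-probability model is invariant
# to a common shift within a family.

SS_CLASSES <- c("HELIX", "SHEET", "TURN", "OTHER")

#' Build the standard genetic code with synonymous-family structure
#'
#' Returns the standard genetic code together with the synonymous-family
#' decomposition used throughout the package: for every family the codons
#' are sorted lexicographically and the last codon is the designated
#' reference (its mutation-bias offset \eqn{\Delta M} and selection offset
#' \eqn{\Delta\eta} are fixed at 0).
#'
#' Serine is treated as a single 6-codon family by default. With
#' `split_serine = TRUE` it is split into the TCN four-codon family
#' (labelled `"S"`) and the AGC/AGT two-codon family (labelled `"Z"`),
#' reflecting that the two codon blocks are not reachable from each other
#' by single synonymous substitutions. Translation always reports `"S"`.
#'
#' @param split_serine logical; split serine into TCN and AGY sub-families.
#' @return An object of class `genetic_code`: a list with elements
#'   `table` (named character, codon -> amino acid or `"*"`), `families`
#'   (named list, family label -> sorted codons), `reference` (named
#'   character, family label -> reference codon), `family_of` (named
#'   character, sense codon -> family label), `single_codon_families`
#'   (family labels with one codon, untestable for synonymous
#'   comparisons), and `split_serine`.
#' @examples
#' code <- genetic_code()
#' code$families[["V"]]   # GTA GTC GTG GTT
#' code$reference[["V"]]  # GTT
#' @export
genetic_code <- function(split_serine = FALSE) {
  tab <- Biostrings::GENETIC_CODE
  tab <- tab[order(names(tab))]
  sense <- tab[tab != "*"]
  fam_label <- unname(sense)
  if (split_serine) {
    fam_label[fam_label == "S" & startsWith(names(sense), "AG")] <- "Z"
  }
  families <- split(names(sense), fam_label)
  families <- lapply(families, sort)
  families <- families[order(names(families))]
  reference <- vapply(families, function(x) x[length(x)], character(1))
  family_of <- stats::setNames(rep(names(families), lengths(families)),
                               unlist(families, use.names = FALSE))
  structure(list(
    table = tab,
    families = families,
    reference = reference,
    family_of = family_of,
    single_codon_families = names(families)[lengths(families) == 1L],
    split_serine = split_serine
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$families), "synonymous families",
      if (x$split_serine) "(serine split into TCN/AGY)" else "(serine as one family)",
      "\n")
  invisible(x)
}

SENSE_CODONS <- function(code) names(code$family_of)

#' Translate a vector of codons to an amino acid string
#'
#' @param codons character vector of sense codons (DNA alphabet, upper case).
#' @param code a [genetic_code()] object.
#' @param gene_id optional label used in error messages.
#' @return single amino acid string, one letter per codon.
#' @export
translate_codons <- function(codons, code = genetic_code(), gene_id = "<unnamed>") {
  if (length(codons) == 0L) return("")
  aa <- code$table[codons]
  bad <- which(is.na(aa) | aa == "*")
  if (length(bad)) {
    stop(sprintf("gene '%s': invalid or stop codon '%s' at codon position %d",
                 gene_id, codons[bad[1L]], bad[1L]), call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Construct a validated set of coding sequences
#'
#' A `codon_seqs` object is a named list of codon vectors, one element per
#' gene. Validation checks that every codon is a sense codon of the
#' standard code and that gene ids are unique.
#'
#' @param x named list of character vectors of codons, or a named
#'   character vector of nucleotide strings (length divisible by 3).
#' @param code a [genetic_code()] object.
#' @return object of class `codon_seqs`.
#' @export
coding_sequences <- function(x, code = genetic_code()) {
  if (is.character(x)) {
    x <- lapply(x, function(s) {
      s <- toupper(s)
      if (nchar(s) %% 3L != 0L) {
        stop("sequence length not divisible by 3", call. = FALSE)
      }
      substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    })
  }
  ids <- names(x)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("all sequences must be named by gene_id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  for (g in ids) translate_codons(x[[g]], code, gene_id = g)  # validates
  structure(x, class = "codon_seqs")
}

#' @export
print.codon_seqs <- function(x, ...) {
  cat(sprintf("codon_seqs: %d genes, %d codons total\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' Translate a set of coding sequences
#'
#' @param seqs a `codon_seqs` object (or named list of codon vectors).
#' @param code a [genetic_code()] object.
#' @return named character vector of amino acid strings.
#' @export
translate_seqs <- function(seqs, code = genetic_code()) {
  vapply(names(seqs), function(g) translate_codons(seqs[[g]], code, g),
         character(1))
}

#' Per-gene codon counts over all sense codons
#'
#' @param seqs a `codon_seqs` object.
#' @param code a [genetic_code()] object.
#' @return integer matrix, genes x 61 sense codons (zeros included);
#'   row sums equal sequence lengths in codons.
#' @export
codon_counts <- function(seqs, code = genetic_code()) {
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  sense <- SENSE_CODONS(code)
  m <- matrix(0L, nrow = length(seqs), ncol = length(sense),
              dimnames = list(ids, sense))
  for (i in seq_along(seqs)) {
    tb <- table(factor(seqs[[i]], levels = sense))
    m[i, ] <- as.integer(tb)
  }
  m
}

#' Read in-frame coding sequences from a nucleotide FASTA file
#'
#' The first whitespace-delimited token of each header is taken as the
#' gene id; sequences are upper-cased. Records failing validation (length
#' not divisible by 3, internal stop codon, non-ACGT base) either abort or
#' are skipped with a warning, per `on_error`.
#'
#' @param path FASTA file.
#' @param code a [genetic_code()] object.
#' @param on_error `"fail"` (default) or `"skip"`.
#' @return a `codon_seqs` object.
#' @export
read_cds_fasta <- function(path, code = genetic_code(), on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  dna <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(dna), "\\s+"), `[`, character(1), 1L)
  out <- list()
  for (i in seq_along(dna)) {
    s <- toupper(as.character(dna[[i]]))
    res <- tryCatch({
      if (grepl("[^ACGT]", s)) stop("non-ACGT base", call. = FALSE)
      if (nchar(s) %% 3L != 0L) stop("length not divisible by 3", call. = FALSE)
      codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
      translate_codons(codons, code, gene_id = ids[i])
      codons
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "fail") {
        stop(sprintf("record '%s': %s", ids[i], conditionMessage(res)),
             call. = FALSE)
      }
      warning(sprintf("skipping record '%s': %s", ids[i],
                      conditionMessage(res)), call. = FALSE)
    } else {
      out[[ids[i]]] <- res
    }
  }
  coding_sequences(out, code)
}

#' Write coding sequences to a FASTA file
#'
#' @param seqs a `codon_seqs` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(dna) <- names(seqs)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a dihedral-record table
#'
#' Tab-separated with header columns `gene_id`, `position` (0-based codon
#' index), `aa`, `codon`, `ss` (one of HELIX/SHEET/TURN/OTHER), `phi_deg`,
#' `psi_deg`. Angles are wrapped onto `[-180, 180)` on ingest.
#'
#' @param path TSV file.
#' @param code a [genetic_code()] object used for validation.
#' @return data.frame of dihedral records.
#' @export
read_dihedral_records <- function(path, code = genetic_code()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_records(df, code)
}

#' Write a dihedral-record table
#' @param records data.frame of dihedral records.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_dihedral_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a dihedral-record data.frame
#'
#' Checks the schema, the secondary-structure alphabet, that each codon
#' translates to its recorded amino acid, and wraps angles to
#' `[-180, 180)`.
#'
#' @param records data.frame.
#' @param code a [genetic_code()] object.
#' @return the validated (angle-wrapped) data.frame.
#' @export
validate_records <- function(records, code = genetic_code()) {
  need <- c("gene_id", "position", "aa", "codon", "ss", "phi_deg", "psi_deg")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(records$ss %in% SS_CLASSES)) {
    stop("ss must be one of ", paste(SS_CLASSES, collapse = "/"), call. = FALSE)
  }
  aa <- code$table[records$codon]
  bad <- which(is.na(aa) | aa != records$aa)
  if (length(bad)) {
    stop(sprintf("record %d (gene '%s'): codon %s does not encode aa %s",
                 bad[1L], records$gene_id[bad[1L]], records$codon[bad[1L]],
                 records$aa[bad[1L]]), call. = FALSE)
  }
  records$phi_deg <- wrap_degrees(records$phi_deg)
  records$psi_deg <- wrap_degrees(records$psi_deg)
  records
}

#' Map DSSP secondary-structure codes to the 4-class scheme
#'
#' H/G/I -> HELIX, E/B -> SHEET, T/S -> TURN, everything else -> OTHER.
#' The mapping can be overridden.
#'
#' @param dssp character vector of single-letter DSSP codes.
#' @param mapping named character vector overriding the default map.
#' @return character vector over HELIX/SHEET/TURN/OTHER.
#' @export
dssp_to_ss4 <- function(dssp, mapping = NULL) {
  default <- c(H = "HELIX", G = "HELIX", I = "HELIX",
               E = "SHEET", B = "SHEET",
               T = "TURN", S = "TURN")
  if (!is.null(mapping)) default[names(mapping)] <- mapping
  out <- default[dssp]
  out[is.na(out)] <- "OTHER"
  unname(out)
}
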