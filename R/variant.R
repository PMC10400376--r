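# Variant-effect estimation: the effect of substitutions is the difference
# between the predicted expression of the mutated and the reference
# sequence, and the drift-style evaluation correlates predicted with
# observed effects grouped by substitution count.

#' Construct a validated variant record
#'
#' @param ref_sequence Reference insert sequence over `{A,C,G,T}`.
#' @param position Integer vector of 0-based substitution positions within
#'   the insert.
#' @param ref,alt Character vectors of reference and alternate bases.
#' @return A `variant_record` object.
#' @export
variant_record <- function(ref_sequence, position = integer(),
                           ref = character(), alt = character()) {
  ref_sequence <- toupper(ref_sequence)
  seq_to_codes(ref_sequence, allow_n = FALSE)
  position <- as.integer(position)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(length(position) == length(ref),
            length(position) == length(alt))
  if (anyDuplicated(position)) stopf("duplicate substitution positions")
  if (any(position < 0 | position >= nchar(ref_sequence)))
    stopf("substitution position outside the sequence")
  have <- if (length(position))
    substring(ref_sequence, position + 1, position + 1) else character()
  bad <- which(have != ref)
  if (length(bad))
    stopf("ref base mismatch at 0-based position %d: sequence has %s, record says %s",
          position[bad[1]], have[bad[1]], ref[bad[1]])
  if (any(!alt %in% c("A", "C", "G", "T")))
    stopf("alt bases must be in {A,C,G,T}")
  structure(list(ref_sequence = ref_sequence, position = position,
                 ref = ref, alt = alt),
            class = "variant_record")
}

#' Apply the substitutions of a variant record
#'
#' @param v A [variant_record].
#' @return The alternate sequence (same length as the reference).
#' @export
apply_variants <- function(v) {
  stopifnot(inherits(v, "variant_record"))
  chars <- strsplit(v$ref_sequence, "", fixed = TRUE)[[1]]
  chars[v$position + 1] <- v$alt
  paste(chars, collapse = "")
}

#' Predicted effect of a variant on expression
#'
#' The effect is `predict(alt) - predict(ref)` using test-time-augmented
#' predictions; positive values mean the substitutions raise expression.
#'
#' @param model A trained predictor.
#' @param v A [variant_record].
#' @param flank A [flank_context].
#' @return Numeric effect (a difference of expressions in bin units).
#' @export
variant_effect <- function(model, v, flank = flank_context()) {
  alt <- apply_variants(v)
  if (identical(alt, v$ref_sequence)) return(0)
  p <- predict_with_tta(model, c(ref = v$ref_sequence, alt = alt), flank)
  p$expression[p$id == "alt"] - p$expression[p$id == "ref"]
}

#' Read a variant table against reference sequences
#'
#' TSV columns: sequence id, 0-based position within the insert, ref base,
#' alt base. Rows sharing an id form one multi-substitution record.
#'
#' @param path Path to the TSV (no header).
#' @param references Named character vector of reference inserts (e.g.
#'   from [read_fasta_sequences()]).
#' @return Named list of [variant_record]s.
#' @export
read_variant_table <- function(path, references) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "position", "ref", "alt"))
  missing <- setdiff(unique(tab$id), names(references))
  if (length(missing))
    stopf("variant id(s) without a reference sequence: %s",
          paste(head(missing, 5), collapse = ", "))
  lapply(split(tab, tab$id), function(g)
    variant_record(references[[g$id[1]]], g$position, g$ref, g$alt))
}

#' Drift-style evaluation of variant-effect predictions
#'
#' For pairs of (reference, mutated) sequences with an observed expression
#' difference and a substitution count, computes the predicted effect for
#' every pair and reports Pearson and Spearman correlations between
#' predicted and observed effects per substitution-count group.
#'
#' @param model A trained predictor.
#' @param pairs Data frame with columns `ref`, `alt`, `observed`
#'   (observed expression difference alt - ref) and `n_subs`.
#' @param flank A [flank_context].
#' @return Data frame per group: `n_subs`, `n`, `pearson`, `spearman`,
#'   `note`; the per-pair predictions are in the `predicted` attribute.
#' @export
drift_evaluation <- function(model, pairs, flank = flank_context()) {
  stopifnot(all(c("ref", "alt", "observed", "n_subs") %in% names(pairs)))
  p_ref <- predict_with_tta(model, pairs$ref, flank)$expression
  p_alt <- predict_with_tta(model, pairs$alt, flank)$expression
  predicted <- p_alt - p_ref
  groups <- sort(unique(pairs$n_subs))
  rows <- lapply(groups, function(g) {
    i <- pairs$n_subs == g
    if (sum(i) < 3)
      return(data.frame(n_subs = g, n = sum(i), pearson = NA_real_,
                        spearman = NA_real_,
                        note = "fewer than 3 pairs"))
    cc <- correlations(predicted[i], pairs$observed[i])
    data.frame(n_subs = g, n = sum(i), pearson = cc$pearson,
               spearman = cc$spearman, note = cc$note %||% "")
  })
  out <- do.call(rbind, rows)
  attr(out, "predicted") <- predicted
  out
}
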