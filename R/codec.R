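# Sequence codec: GPRA tables, promoter records, and the 6-channel encoding
# (A, C, G, T, is_singleton, is_reverse) of 5'-padded 150-bp frames.

SEQ_FRAME <- 150L
CHANNELS <- c("A", "C", "G", "T", "is_singleton", "is_reverse")

# Integer base codes: A=1, C=2, G=3, T=4, N/pad=0.
seq_to_codes <- function(seq, allow_n = TRUE) {
  seq <- toupper(seq)
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T", "N")) - 1L
  bad <- which(is.na(codes) | (!allow_n & codes == 4L))
  if (length(bad))
    stopf("invalid base at position %d of sequence '%s'", bad[1],
          substr(seq, 1, 20))
  codes <- ifelse(codes == 4L, 0L, codes + 1L)
  codes
}

codes_to_seq <- function(codes) {
  paste(c("N", "A", "C", "G", "T")[codes + 1L], collapse = "")
}

# Reverse complement of an integer code vector (N maps to N).
revcomp_codes <- function(codes) {
  rc <- rev(codes)
  ifelse(rc == 0L, 0L, 5L - rc)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @return The reverse-complemented string, uppercase.
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(seq) {
  codes_to_seq(revcomp_codes(seq_to_codes(seq)))
}

#' Constant 5' flank context used to pad inserts to the model frame
#'
#' Promoter inserts are padded from the 5' end with the constant plasmid
#' segment so every encoded sequence has the same 150-bp frame. The true
#' plasmid flank is assay-specific, so the default is an all-`N` policy
#' region: unpadded positions encode as all-zero nucleotide columns and
#' carry no invented sequence content.
#'
#' @param five_prime_flank DNA string over `{A,C,G,T,N}` supplying bases
#'   immediately 5' of the insert; its 3'-most bases are used. Shorter
#'   flanks are left-extended with `N`.
#' @param frame Total encoded frame length in base pairs.
#' @return An object of class `flank_context`.
#' @export
flank_context <- function(five_prime_flank = strrep("N", SEQ_FRAME),
                          frame = SEQ_FRAME) {
  codes <- seq_to_codes(five_prime_flank, allow_n = TRUE)
  if (length(codes) < frame)
    codes <- c(rep(0L, frame - length(codes)), codes)
  structure(list(codes = codes, frame = as.integer(frame)),
            class = "flank_context")
}

#' @export
print.flank_context <- function(x, ...) {
  cat(sprintf("<flank_context> frame %d bp, flank %s\n", x$frame,
              substr(codes_to_seq(tail(x$codes, 30)), 1, 30)))
  invisible(x)
}

# Pad insert codes from the 5' end with flank codes to the frame length.
pad_codes <- function(insert_codes, flank) {
  need <- flank$frame - length(insert_codes)
  if (need < 0)
    stopf("insert length %d exceeds the %d-bp frame",
          length(insert_codes), flank$frame)
  c(tail(flank$codes, need), insert_codes)
}

#' Construct a set of promoter records
#'
#' A promoter record couples an insert sequence with its measured
#' expression (a weighted average of sorting-bin numbers, 0-17) and a
#' singleton flag marking sequences observed in a single cell, whose
#' expression estimate is an integer and noisier.
#'
#' @param insert Character vector of insert sequences over `{A,C,G,T}`.
#' @param expression Numeric vector of expression values in `[0, 17]`.
#' @param is_singleton Logical vector; if `NULL`, singletons are detected
#'   by expression integrality (tolerance `1e-6`).
#' @return A `data.frame` with columns `insert`, `expression`,
#'   `is_singleton`, of class `gpra_records`.
#' @export
gpra_records <- function(insert, expression, is_singleton = NULL) {
  insert <- toupper(as.character(insert))
  expression <- as.numeric(expression)
  if (length(insert) != length(expression))
    stopf("insert and expression lengths differ")
  bad <- grep("[^ACGT]", insert)
  if (length(bad))
    stopf("record %d: insert contains a non-ACGT character", bad[1])
  if (length(insert) && (any(!is.finite(expression)) ||
      any(expression < 0 | expression > 17)))
    stopf("expression values must be finite and within [0, 17]")
  if (is.null(is_singleton))
    is_singleton <- abs(expression - round(expression)) <= 1e-6
  out <- data.frame(insert = insert, expression = expression,
                    is_singleton = as.logical(is_singleton),
                    stringsAsFactors = FALSE)
  class(out) <- c("gpra_records", "data.frame")
  out
}

#' Read a GPRA sequence/expression table
#'
#' Reads the plain TSV dialect `sequence<TAB>expression[<TAB>is_singleton]`
#' (no header).
#'
#' @param path Path to the TSV file.
#' @param singleton_mode `"auto"` detects singletons by expression
#'   integrality, `"column"` reads a third 0/1 column, `"none"` marks all
#'   records non-singleton.
#' @return A [gpra_records] data frame in file order.
#' @export
read_gpra_table <- function(path,
                            singleton_mode = c("auto", "column", "none")) {
  singleton_mode <- match.arg(singleton_mode)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (!length(lines))
    return(gpra_records(character(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (singleton_mode == "column") 3L else 2L
  bad <- which(nf < need)
  if (length(bad))
    stopf("parse error at line %d of %s: expected >= %d tab-separated fields",
          which(keep)[bad[1]], path, need)
  seqs <- vapply(fields, `[[`, "", 1L)
  expr <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(is.na(expr))
  if (length(bad))
    stopf("parse error at line %d of %s: expression is not numeric",
          which(keep)[bad[1]], path)
  singles <- switch(singleton_mode,
    auto = NULL,
    column = as.logical(as.integer(vapply(fields, `[[`, "", 3L))),
    none = rep(FALSE, length(seqs)))
  gpra_records(seqs, expr, singles)
}

#' Write a GPRA sequence/expression table
#'
#' @param records A [gpra_records] data frame.
#' @param path Output path.
#' @param singleton_column Write the singleton flag as a third 0/1 column.
#' @return `path`, invisibly.
#' @export
write_gpra_table <- function(records, path, singleton_column = TRUE) {
  lines <- if (singleton_column)
    sprintf("%s\t%s\t%d", records$insert,
            format(records$expression, trim = TRUE, digits = 15),
            as.integer(records$is_singleton))
  else
    sprintf("%s\t%s", records$insert,
            format(records$expression, trim = TRUE, digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings][Biostrings::readDNAStringSet] for
#' prediction-only inputs.
#'
#' @param path Path to a (multi-record, possibly line-wrapped) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stopf("reading FASTA requires the Biostrings package")
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

# Batch one-hot encoder. codes: frame x B integer matrix; singleton,
# reverse: length-B 0/1 vectors. Returns a (6, frame, B) array.
encode_codes_batch <- function(codes, singleton, reverse) {
  L <- nrow(codes); B <- ncol(codes)
  arr <- array(0, dim = c(6L, L, B))
  nz <- which(codes > 0L)
  if (length(nz)) {
    pos <- ((nz - 1L) %% L) + 1L
    smp <- ((nz - 1L) %/% L) + 1L
    arr[cbind(codes[nz], pos, smp)] <- 1
  }
  arr[5L, , ] <- rep(as.numeric(singleton), each = L)
  arr[6L, , ] <- rep(as.numeric(reverse), each = L)
  arr
}

#' Encode a promoter record into the 6-channel model input
#'
#' The insert is padded from the 5' end with the flank context to a fixed
#' 150-bp frame and one-hot encoded over four nucleotide channels; two
#' constant channels carry the singleton flag and the orientation. For the
#' reverse-complement orientation the entire padded frame is
#' reverse-complemented and the `is_reverse` channel set to 1.
#'
#' @param insert Insert sequence over `{A,C,G,T}`, length 1-150.
#' @param orientation `"forward"` or `"reverse_complement"`.
#' @param flank A [flank_context]; `N` flank bases encode as all-zero
#'   nucleotide columns.
#' @param is_singleton Logical singleton flag (training-time only).
#' @return A 6 x 150 numeric matrix with rownames
#'   `A, C, G, T, is_singleton, is_reverse`.
#' @export
encode_promoter <- function(insert,
                            orientation = c("forward", "reverse_complement"),
                            flank = flank_context(),
                            is_singleton = FALSE) {
  orientation <- match.arg(orientation)
  codes <- pad_codes(seq_to_codes(insert, allow_n = FALSE), flank)
  rev <- orientation == "reverse_complement"
  if (rev) codes <- revcomp_codes(codes)
  m <- encode_codes_batch(matrix(codes, ncol = 1), as.numeric(is_singleton),
                          as.numeric(rev))[, , 1]
  rownames(m) <- CHANNELS
  m
}

#' Decode the nucleotide channels of an encoded sequence
#'
#' @param mat A 6 x L (or 4 x L) encoding matrix.
#' @return The decoded sequence string; all-zero columns decode to `N`.
#' @export
decode_encoding <- function(mat) {
  nuc <- mat[1:4, , drop = FALSE]
  codes <- apply(nuc, 2, function(col) {
    i <- which(col == 1)
    if (length(i) == 1) i else 0L
  })
  codes_to_seq(as.integer(codes))
}

#' Encode a sequence for inference in both orientations
#'
#' Inference always uses `is_singleton = 0`; predictions are averaged over
#' the forward and reverse-complement encodings (test-time augmentation).
#'
#' @inheritParams encode_promoter
#' @param sequence Insert sequence over `{A,C,G,T}`.
#' @return List with elements `forward` and `reverse`, each a 6 x 150
#'   matrix differing in the `is_reverse` channel.
#' @export
inference_encode <- function(sequence, flank = flank_context()) {
  list(
    forward = encode_promoter(sequence, "forward", flank, is_singleton = FALSE),
    reverse = encode_promoter(sequence, "reverse_complement", flank,
                              is_singleton = FALSE)
  )
}
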