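test_that("singleton auto-detection follows the integrality rule", {
  r <- gpra_records(c(strrep("ACGT", 20), strrep("ACGT", 20)),
                    c(11.0, 10.5))
  expect_equal(r$is_singleton, c(TRUE, FALSE))
  # explicit flags override detection
  r2 <- gpra_records("ACGT", 5, is_singleton = FALSE)
  expect_false(r2$is_singleton)
})

test_that("gpra_records validates alphabet and expression range", {
  expect_error(gpra_records("ACGU", 3), "non-ACGT")
  expect_error(gpra_records("ACGT", 18.2), "\\[0, 17\\]")
  expect_error(gpra_records("ACGT", NA_real_), "finite")
})

test_that("GPRA table round trips through the TSV dialect", {
  set.seed(1)
  recs <- gpra_records(random_insert(20), round(runif(20, 0, 17), 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gpra_table(recs, path)
  back <- read_gpra_table(path, singleton_mode = "column")
  expect_equal(back, recs)
  # auto mode re-detects the same flags (integrality)
  expect_equal(read_gpra_table(path, "auto")$is_singleton, recs$is_singleton)
})

test_that("table reader handles empty files and malformed lines", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), path)
  expect_equal(nrow(read_gpra_table(path)), 0L)
  writeLines(c("ACGT\t3.5", "ACGTonly"), path)
  expect_error(read_gpra_table(path), "line 2")
  writeLines("ACGT\tnotanumber", path)
  expect_error(read_gpra_table(path), "not numeric")
  writeLines("ACGT\t99", path)
  expect_error(read_gpra_table(path), "\\[0, 17\\]")
})

test_that("an 80-nt insert encodes into the fixed 150-bp 6-channel frame", {
  ins <- random_insert(1)
  m <- encode_promoter(ins, "forward", flank_context(), is_singleton = TRUE)
  expect_equal(dim(m), c(6L, 150L))
  sums <- colSums(m[1:4, ])
  # all-N flank -> zero columns for 70 padded positions, one-hot elsewhere
  expect_equal(sums, c(rep(0, 70), rep(1, 80)))
  expect_equal(unique(m[5, ]), 1)  # is_singleton broadcast
  expect_equal(unique(m[6, ]), 0)  # forward orientation
})

test_that("real flank bases fill the padded frame and decode back", {
  flank <- flank_context(strrep("GATTACA", 30))  # 210 nt, 3'-most used
  ins <- random_insert(1, 80)
  m <- encode_promoter(ins, "forward", flank)
  expect_true(all(colSums(m[1:4, ]) == 1))
  dec <- decode_encoding(m)
  expect_equal(substr(dec, 71, 150), ins)
  expect_equal(nchar(dec), 150L)
})

test_that("reverse-complement encoding equals reversal plus channel swap", {
  ins <- random_insert(1)
  fw <- encode_promoter(ins, "forward")
  rc <- encode_promoter(ins, "reverse_complement")
  swapped <- unname(fw[c(4L, 3L, 2L, 1L, 5L, 6L), 150:1])
  expect_equal(unname(rc[1:5, ]), swapped[1:5, ])
  expect_equal(unique(rc[6, ]), 1)
  # double reverse complement is the identity on the sequence
  expect_equal(reverse_complement(reverse_complement(ins)), ins)
  expect_equal(decode_encoding(rc), reverse_complement(decode_encoding(fw)))
})

test_that("inference encoding is singleton-free and orientation-paired", {
  pair <- inference_encode(random_insert(1))
  expect_equal(unique(pair$forward[5, ]), 0)
  expect_equal(unique(pair$reverse[5, ]), 0)
  expect_equal(unique(pair$forward[6, ]), 0)
  expect_equal(unique(pair$reverse[6, ]), 1)
})

test_that("palindromic frames give identical nucleotide channels", {
  half <- random_insert(1, 40)
  pal <- paste0(half, reverse_complement(half))
  pair <- inference_encode(pal, desk_flank())
  expect_equal(pair$forward[1:4, ], pair$reverse[1:4, ])
})

test_that("encoding rejects invalid input", {
  expect_error(encode_promoter(strrep("A", 151)), "exceeds")
  expect_error(encode_promoter("ACGN"), "invalid base")
})

test_that("FASTA sequences round trip through the reader", {
  skip_if_not_installed("Biostrings")
  path <- withr::local_tempfile(fileext = ".fa")
  seqs <- stats::setNames(random_insert(3), c("p1", "p2", "p3"))
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), substr(seqs[[n]], 1, 40), substr(seqs[[n]], 41, 80)))),
    path)
  back <- read_fasta_sequences(path)
  expect_equal(back, seqs)
})
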