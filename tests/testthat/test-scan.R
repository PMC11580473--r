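test_that("Z-DNA scanner finds maximal alternating tracts", {
  p <- scan_params()
  h <- scan_zdna("GCGCGCGCGC", "s", p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 1L)
  expect_equal(h$stop, 10L)
  expect_equal(h$length, 10L)
  expect_equal(h$motif_class, "ZDNA")

  # a (TG)19 tract with non-alternating flanks: flanking A runs cannot
  # extend it (A-T steps are excluded and G->A does not alternate)
  zp1 <- paste0(strrep("A", 100), strrep("TG", 19), strrep("A", 100))
  h <- scan_zdna(zp1, "pen", p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 101L)
  expect_equal(h$stop, 138L)
  expect_equal(h$length, 38L)

  # the A-T step splits this into two 5-nt tracts, below the threshold
  expect_equal(nrow(scan_zdna("ACACATACAC", "s", p)), 0L)

  expect_equal(nrow(scan_zdna("", "s", p)), 0L)
  expect_error(scan_zdna("ACGT", "", p), "seq_id")
  expect_error(scan_zdna("ACGT", "s", list()), "scan_params")
})

test_that("scanner parameter validation enforces the documented bounds", {
  expect_error(scan_params(zdna_min_len = 1), "zdna_min_len")
  expect_error(scan_params(str_unit_min = 0), "str_unit")
  expect_error(scan_params(str_unit_min = 4, str_unit_max = 3), "str_unit")
  expect_error(scan_params(str_unit_max = 10), "str_unit")
  expect_error(scan_params(str_min_copies = 1), "str_min_copies")
})

test_that("STR scanner reports primitive units, copies and partial tails", {
  p <- scan_params()
  h <- scan_str("ACACACACACAC", "s", p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$unit, "AC")
  expect_equal(h$copies, 6L)
  expect_equal(c(h$start, h$stop), c(1L, 12L))

  # mononucleotide runs are excluded by the default unit range
  expect_equal(nrow(scan_str("AAAAAAAAAA", "s", p)), 0L)

  # partial trailing copy extends the tract but not the copy count
  h <- scan_str("GATGATGATG", "s", p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$unit, "GAT")
  expect_equal(h$copies, 3L)
  expect_equal(c(h$start, h$stop), c(1L, 10L))

  # copies always equals floor(length / unit length)
  set.seed(7)
  for (i in 1:20) {
    h <- scan_str(rand_seq(300), "s",
                  scan_params(str_min_copies = 2, str_min_len = 6))
    if (nrow(h) > 0L)
      expect_equal(h$copies, h$length %/% nchar(h$unit))
  }
})

test_that("soft-masked bases are scanned by default and excluded on demand", {
  soft <- paste0("acac", "GCGCGCGCGC", "acac")
  h <- scan_zdna(soft, "s", scan_params(zdna_min_len = 6))
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$stop), c(1L, 18L))
  h2 <- scan_zdna(soft, "s",
                  scan_params(zdna_min_len = 6, include_softmasked = FALSE))
  expect_equal(c(h2$start, h2$stop), c(5L, 14L))
  expect_equal(nrow(scan_str("acacacacacac", "s",
                             scan_params(include_softmasked = FALSE))), 0L)
})

test_that("non-ACGT symbols terminate tracts", {
  p <- scan_params(zdna_min_len = 4, str_min_len = 4, str_min_copies = 2)
  set.seed(11)
  n_checked <- 0L
  while (n_checked < 15L) {
    s <- rand_seq(300)
    hz <- rbind(scan_zdna(s, "s", p), scan_str(s, "s", p))
    if (nrow(hz) == 0L) next
    h <- hz[sample.int(nrow(hz), 1L), ]
    mid <- (h$start + h$stop) %/% 2L
    s2 <- paste0(substr(s, 1L, mid - 1L), "N",
                 substr(s, mid + 1L, nchar(s)))
    h2 <- rbind(scan_zdna(s2, "s", p), scan_str(s2, "s", p))
    # no surviving hit spans the N position
    expect_true(all(h2$start > mid | h2$stop < mid))
    n_checked <- n_checked + 1L
  }
})

test_that("Z-DNA hits are maximal, non-overlapping and strand symmetric", {
  p <- scan_params(zdna_min_len = 6)
  set.seed(21)
  for (i in 1:30) {
    s <- rand_seq(500)
    h <- scan_zdna(s, "s", p)
    if (nrow(h) > 1L)
      expect_true(all(h$start[-1L] > h$stop[-nrow(h)]))
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
    hr <- scan_zdna(rc, "s", p)
    n <- nchar(s)
    expect_equal(sort(n - h$stop + 1L), sort(hr$start))
    expect_equal(sort(n - h$start + 1L), sort(hr$stop))
  }
})

test_that("STR hits with the same unit never overlap", {
  p <- scan_params(str_min_copies = 2, str_min_len = 4)
  set.seed(31)
  for (i in 1:30) {
    h <- scan_str(rand_seq(600), "s", p)
    for (u in unique(h$unit)) {
      hu <- h[h$unit == u, , drop = FALSE]
      if (nrow(hu) > 1L) {
        hu <- hu[order(hu$start), ]
        expect_true(all(hu$start[-1L] > hu$stop[-nrow(hu)]))
      }
    }
  }
})

test_that("scanners agree with the exhaustive substring oracle (small k)", {
  relaxed <- scan_params(zdna_min_len = 4, str_unit_min = 2,
                         str_unit_max = 3, str_min_copies = 2,
                         str_min_len = 4)
  for (k in c(4L, 6L, 7L)) {
    M <- all_seq_matrix(k)
    expect_identical(hit_set_key(oracle_zdna_batch(M, relaxed)),
                     hit_set_key(scan_batch(M, scan_zdna, relaxed)))
    expect_identical(hit_set_key(oracle_str_batch(M, relaxed)),
                     hit_set_key(scan_batch(M, scan_str, relaxed)))
  }
  # the vectorized oracle itself agrees with the naive per-substring one
  set.seed(41)
  for (i in 1:25) {
    s <- rand_seq(9)
    o1 <- oracle_zdna_small(s, relaxed)
    o2 <- oracle_zdna_batch(matrix(seq_codes(s), 1L), relaxed)
    k1 <- if (is.null(o1)) character(0) else
      sort(paste(o1[, 1L], o1[, 2L]))
    expect_identical(k1, sort(paste(o2$start, o2$stop)))
  }
})

test_that("motif TSV round-trips exactly and validates on read", {
  p <- scan_params(zdna_min_len = 6, str_min_copies = 2, str_min_len = 6)
  set.seed(51)
  hits <- do.call(rbind, lapply(1:40, function(i) {
    s <- rand_seq(800)
    rbind(scan_zdna(s, paste0("ctg", i), p),
          scan_str(s, paste0("ctg", i), p))
  }))
  expect_gt(nrow(hits), 100L)
  rownames(hits) <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_tsv(hits, path)
  expect_identical(read_motif_tsv(path), hits)

  # header-only file round-trips the empty collection
  write_motif_tsv(hits[0L, ], path)
  expect_equal(readLines(path), paste(c("Sequence_name", "Source", "Type",
                                        "Start", "Stop", "Length", "Unit",
                                        "Copies", "Sequence"),
                                      collapse = "\t"))
  expect_equal(nrow(read_motif_tsv(path)), 0L)

  # single hit -> header + one record
  write_motif_tsv(hits[1L, ], path)
  expect_length(readLines(path), 2L)

  # malformed content errors name the line
  writeLines(c(paste(c("Sequence_name", "Source", "Type", "Start", "Stop",
                       "Length", "Unit", "Copies", "Sequence"),
                     collapse = "\t"),
               "chr1\tx\tZDNA\t5\t2\t4\t\t\tACGT"), path)
  expect_error(read_motif_tsv(path), "line 2.*Stop < Start")
  writeLines(c(paste(c("Sequence_name", "Source", "Type", "Start", "Stop",
                       "Length", "Unit", "Copies", "Sequence"),
                     collapse = "\t"),
               "chr1\tonly\tthree"), path)
  expect_error(read_motif_tsv(path), "line 2")
  expect_error(write_motif_tsv(data.frame(seq_id = "a", start = 5L,
                                          stop = 2L, length = 4L,
                                          motif_class = "ZDNA", unit = "",
                                          copies = NA_integer_,
                                          sequence = "ACGT"),
                               path), "Stop < Start")
})

test_that("scan_fasta applies both scanners across records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(c1 = strrep("TG", 10), c2 = strrep("GAT", 5)), fa)
  h <- scan_fasta(fa)
  expect_setequal(unique(h$seq_id), c("c1", "c2"))
  expect_setequal(unique(h$motif_class), c("ZDNA", "STR"))
  hz <- scan_fasta(fa, classes = "ZDNA")
  expect_true(all(hz$motif_class == "ZDNA"))
})
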