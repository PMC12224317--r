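mature <- function(n = 300) strrep("DENQ", ceiling(n / 4))

test_that("TAT detection requires the twin-arginine consensus plus h-region", {
  expect_identical(detectTatSignal(paste0("M", strrep("K", 99)))$type, "none")

  tat <- paste0("MSTRRNFLK", "AAVLLGALAG", mature(100))
  call <- detectTatSignal(tat)
  expect_identical(call$type, "TAT")
  expect_identical(call$motif_position, 3L)

  # consensus far downstream is not a signal peptide
  late <- paste0(strrep("DE", 100), "STRRNFAAAAAALLL", mature(50))
  expect_identical(detectTatSignal(late)$type, "none")

  # consensus without a following hydrophobic run fails
  nohyd <- paste0("MSTRRNFLK", strrep("DE", 60))
  expect_identical(detectTatSignal(nohyd)$type, "none")

  expect_error(detectTatSignal("MSTRRXFLK"), "non-amino-acid")
  expect_error(detectTatSignal("MSTRR"), "too short")
})

test_that("Sec detection matches PelB and excludes TAT-positive sequences", {
  pelb <- paste0("MKYLLPTAAAGLLLLAAQPAMA", mature(100))
  expect_identical(detectSecSignal(pelb)$type, "Sec")
  expect_identical(detectSecSignal(paste0(strrep("S", 40), mature(60)))$type,
                   "none")
  tat <- paste0("MSTRRNFLK", "AAVLLGALAG", mature(100))
  expect_identical(detectSecSignal(tat)$type, "none")
})

test_that("TAT and Sec calls are mutually exclusive on random sequences", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:50) {
    s <- paste(sample(aa, 80, TRUE), collapse = "")
    both <- c(detectTatSignal(s)$type, detectSecSignal(s)$type)
    expect_false(all(both == c("TAT", "Sec")))
  }
})

test_that("heme-motif counting assigns cytochrome classes by count and size", {
  none <- detectCytc(strrep("KDEN", 30))
  expect_identical(none$class, "not_cytc")
  expect_identical(none$motif_count, 0L)

  mono <- detectCytc(paste0(strrep("K", 40), "CAGCH", strrep("K", 55)))
  expect_identical(mono$class, "class_I_monoheme")
  expect_identical(mono$motif_positions, 41L)

  c4 <- detectCytc(paste0(strrep("K", 50), "CAGCH", strrep("K", 70),
                          "CTTCH", strrep("K", 55)))
  expect_identical(c4$class, "c4_diheme")
  expect_identical(c4$motif_count, 2L)

  # single motif in a large protein is not called a cytochrome
  big <- detectCytc(paste0(strrep("K", 200), "CAGCH", strrep("K", 200)))
  expect_identical(big$class, "not_cytc")
})

test_that("fusion detection needs length, C-terminal heme motif and TAT", {
  lead <- paste0("MSTRRNFLK", "AAVLLGALAG")
  fused <- paste0(lead, strrep("D", 400), "CAGCH", strrep("D", 60))
  expect_true(detectFusion(fused))
  nofuse <- paste0(lead, strrep("D", 465))
  expect_false(detectFusion(nofuse))
  small_cytc <- paste0("M", strrep("D", 60), "CAGCH", strrep("D", 55))
  expect_false(detectFusion(small_cytc))   # below the FAO length floor
  # heme motif too far from the C-terminus does not count
  early <- paste0(lead, "CAGCH", strrep("D", 460))
  expect_false(detectFusion(early))
})

test_that("operon context assigns the four categories and honors the window", {
  ops <- genSyntheticOperons(c("black", "blue", "green", "red"), seed = 3)
  fao_idx <- which(grepl("amine oxidoreductase", ops$records$product))
  got <- vapply(fao_idx, function(i)
    scanFaoContext(ops$records, i)$category, character(1))
  loci <- ops$records$locus[fao_idx]
  expect_identical(unname(got),
                   ops$truth$category[match(loci, ops$truth$locus)])

  # nearest cytochrome outside the bp window: blue degrades to red
  blue_i <- fao_idx[got == "blue"]
  rec <- ops$records[ops$records$contig ==
                       ops$records$contig[blue_i], , drop = FALSE]
  shift <- rec$locus == rec$locus[which(grepl("cytochrome", rec$product))[1]]
  rec$start[shift] <- rec$start[shift] + 10000L
  rec$end[shift] <- rec$end[shift] + 10000L
  i2 <- which(grepl("amine oxidoreductase", rec$product))
  expect_identical(scanFaoContext(rec, i2)$category, "red")

  expect_error(scanFaoContext(ops$records[0, ], 1), "non-empty")
})

test_that("pairwise identity counts matches over aligned columns", {
  a <- strrep("MKVLITAGDE", 10)
  expect_equal(pairwiseIdentity(a, a), 1.0)
  expect_equal(pairwiseIdentity("AAAA", "TTTT"), 0.0)
  b <- paste0(substr(a, 1, 50), "W", substr(a, 52, 100))
  expect_equal(pairwiseIdentity(a, b), 0.99)
  expect_error(pairwiseIdentity("", a), "single character|non-amino|empty")
})

test_that("dedupe keeps one of a 99% pair, both of a 97% pair, and is idempotent", {
  base <- strrep("MKVLITAGDE", 10)
  mut <- function(s, at) {
    for (i in at) substr(s, i, i) <- "W"
    s
  }
  seqs <- c(a = base, b = mut(base, 5), c = mut(base, c(11, 25, 37)),
            d = strrep("FYPSNHQC", 12))
  # b is 99% identical to a (dropped); c is 97% (kept); d unrelated (kept)
  res <- dedupeByIdentity(seqs, cutoff = 0.98)
  expect_identical(res$kept, c("a", "c", "d"))
  expect_identical(unname(res$cluster[["b"]]), 1L)

  res2 <- dedupeByIdentity(seqs[res$kept], cutoff = 0.98)
  expect_identical(res2$kept, res$kept)
  expect_lte(length(res$kept), length(seqs))

  expect_identical(dedupeByIdentity(c(x = base, y = base))$kept, "x")
})

test_that("GenBank round-trip preserves gene records", {
  ops <- genSyntheticOperons(c("blue", "black"), seed = 9)
  f <- tempfile(fileext = ".gbk")
  writeGenBankFeatures(ops$records, f)
  back <- readGenBankFeatures(f)
  expect_identical(back$locus, ops$records$locus)
  expect_identical(back$start, ops$records$start)
  expect_identical(back$end, ops$records$end)
  expect_identical(back$strand, ops$records$strand)
  expect_identical(back$protein, ops$records$protein)
  expect_identical(back$product, ops$records$product)
  unlink(f)
})

test_that("FASTA round-trip preserves sequences and names", {
  seqs <- c(p1 = "MKVLITAGDE", p2 = "FYPSNHQCWA")
  f <- tempfile(fileext = ".faa")
  writeProteinFasta(seqs, f)
  expect_identical(readProteinFasta(f), seqs)
  unlink(f)
})
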