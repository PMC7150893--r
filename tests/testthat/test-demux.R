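test_that("FASTQ to FASTA conversion conserves records, ids and bases", {
  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(), tmp)
  expect_equal(nrow(read_fastq(tmp)), 0L)
  reads <- data.frame(read_id = c("a", "b", "c"),
                      bases = c("ACGT", "GGGG", "TTAACC"),
                      stringsAsFactors = FALSE)
  write_fastq(reads, tmp)
  back <- convert_fastq_to_fasta(tmp)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$bases, reads$bases)
  fa <- withr::local_tempfile(fileext = ".fasta")
  convert_fastq_to_fasta(tmp, out = fa)
  expect_identical(read_fasta(fa), back)
})

test_that("malformed FASTQ is reported with a line number", {
  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), tmp)
  expect_error(read_fastq(tmp), "line 5")
  writeLines(c("r1", "ACGT", "+", "IIII"), tmp)
  expect_error(read_fastq(tmp), "line 1")
  writeLines(c("@r1", "ACGT", "+", "III"), tmp)
  expect_error(read_fastq(tmp), "length mismatch at line 2")
})

test_that("MID assignment matches the documented decoration and ambiguity rules", {
  mani <- vostok_mid_manifest()
  glacial <- mani[mani$sample_label == "2149m", ]
  rd <- decorated_read(glacial, strrep("ACGT", 20))
  asg <- assign_by_mid(rd, mani, max_mismatch = 0)
  expect_equal(asg$bins[["2149m"]]$read_id, "r1")
  # a read of all A matches no MID
  junk <- data.frame(read_id = "j", bases = strrep("A", 120),
                     stringsAsFactors = FALSE)
  asg2 <- assign_by_mid(junk, mani)
  expect_equal(nrow(asg2$unassigned), 1L)
  # a read containing two different MIDs equally well is ambiguous
  two <- data.frame(read_id = "amb",
                    bases = paste0(mani$mid[1], mani$mid[2], strrep("G", 60)),
                    stringsAsFactors = FALSE)
  asg3 <- assign_by_mid(two, mani, max_mismatch = 0)
  expect_equal(asg3$unassigned$read_id, "amb")
  # one substitution in the MID: rejected at 0 mismatches, rescued at 1
  mut <- decorated_read(glacial, strrep("C", 60))$bases
  substr(mut, 31L, 31L) <- "T"  # first MID base (adapter is 30 nt)
  mutr <- data.frame(read_id = "m", bases = mut, stringsAsFactors = FALSE)
  expect_equal(nrow(assign_by_mid(mutr, mani, max_mismatch = 0)$unassigned), 1L)
  expect_equal(assign_by_mid(mutr, mani, max_mismatch = 1)$bins[["2149m"]]$read_id,
               "m")
  expect_error(assign_by_mid(rd, mid_manifest(c("a", "b"),
                                              c("ACGCTCGACA", "ACGCTCGACA"))),
               "duplicate")
})

test_that("clipping removes 5' decoration exactly and 3' adapters when present", {
  mani <- vostok_mid_manifest()
  entry <- mani[2L, ]
  insert <- strrep("ACGT", 15)  # 60 nt
  rd <- decorated_read(entry, insert)
  asg <- assign_by_mid(rd, mani)
  cl <- clip_decoration(asg$bins[[entry$sample_label]], entry)
  expect_identical(cl$reads$bases, insert)
  # the linker is gone from the output
  expect_false(grepl(entry$linker, cl$reads$bases, fixed = TRUE))
  # 3' P1 adapter (reverse complement) is trimmed when present
  rc_p1 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(entry$adapter_p1)))
  rd3 <- decorated_read(entry, paste0(insert, rc_p1, "ACGT"), id = "r3")
  asg3 <- assign_by_mid(rd3, mani)
  cl3 <- clip_decoration(asg3$bins[[entry$sample_label]], entry)
  expect_identical(cl3$reads$bases, insert)
  # clip to nothing goes to the discard list, not an error
  rd0 <- decorated_read(entry, "", id = "r0")
  asg0 <- assign_by_mid(rd0, mani)
  cl0 <- clip_decoration(asg0$bins[[entry$sample_label]], entry)
  expect_equal(nrow(cl0$reads), 0L)
  expect_equal(cl0$fully_clipped$read_id, "r0")
})

test_that("the length filter keeps 50 bp and drops 49 bp", {
  reads <- data.frame(read_id = c("keep", "drop"),
                      bases = c(strrep("A", 50), strrep("A", 49)),
                      stringsAsFactors = FALSE)
  fl <- filter_min_length(reads, 50)
  expect_identical(fl$reads$read_id, "keep")
  expect_equal(fl$discarded, 1L)
})

test_that("end-to-end demux on zero-error reads reproduces the truth map", {
  spec <- tiny_spec(n_reads = 250L, seed = 17, insert_range = c(40L, 120L))
  sim <- simulate_reads(spec)
  dm <- demultiplex(sim$reads, vostok_mid_manifest(), min_len = 50)
  # partition: every read is in exactly one bin
  expect_equal(sum(dm$report$assigned) + nrow(dm$unassigned), nrow(sim$reads))
  expect_equal(dm$report$assigned,
               dm$report$retained + dm$report$short + dm$report$fully_clipped)
  expect_equal(nrow(dm$unassigned), 0L)
  # retained reads equal the truth inserts of length >= 50, per sample
  for (s in names(dm$samples)) {
    keep <- sim$truth[sim$truth$sample_label == s &
                        sim$truth$insert_length >= 50, ]
    expect_identical(dm$samples[[s]]$read_id, keep$read_id)
    expect_identical(dm$samples[[s]]$bases, keep$insert)
  }
  # short-discard bookkeeping matches a brute-force count
  expect_equal(sum(dm$report$short),
               sum(sim$truth$insert_length < 50))
})
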