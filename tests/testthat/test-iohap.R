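# Alignment and haplotype-table I/O and haplotype collapsing.

test_that("read_alignment parses FASTA and rejects bad input", {
  tf <- write_tmp_fasta(c(a = "ACGTACGTAC", b = "ACGTACGTAT",
                          c = "CCGTACGTAC"))
  aln <- read_alignment(tf)
  expect_equal(dim(as.matrix(aln)), c(3L, 10L))
  expect_setequal(rownames(as.matrix(aln)), c("a", "b", "c"))

  ragged <- write_tmp_fasta(c(a = "ACGTACGTA", b = "ACGTACGTAT"))
  expect_error(read_alignment(ragged), "alignment error")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_alignment(empty), "input error")
  expect_error(read_alignment(tempfile()), "input error")
})

test_that("alignment write -> read round-trips simulator output", {
  d <- simulate_dataset(demography_constant(3, 6, L = 80), seed = 5)
  tf <- tempfile(fileext = ".fasta")
  write_alignment(d$alignment, tf)
  back <- read_alignment(tf)
  expect_identical(as.character(as.matrix(back)),
                   as.character(as.matrix(d$alignment)))
})

test_that("collapse_haplotypes groups identical retained-site sequences", {
  # n copies of one sequence -> one haplotype
  same <- char_aln(setNames(rep("ACGT", 5), paste0("s", 1:5)))
  h <- collapse_haplotypes(same)
  expect_equal(length(h$counts), 1L)
  expect_equal(unname(h$counts), 5L)

  toy <- char_aln(c(s1 = "AAAA", s2 = "AAAT", s3 = "AAAT", s4 = "CAAA"))
  h <- collapse_haplotypes(toy)
  expect_equal(unname(h$counts), c(1L, 2L, 1L))
  expect_equal(unname(h$labels),
               c("H01", "H02", "H02", "H03")) # first-appearance order

  # every sequence unique -> Nhap = n
  uniq <- char_aln(setNames(c("AAAA", "AAAC", "AAAG", "AATA"),
                            paste0("u", 1:4)))
  expect_equal(length(collapse_haplotypes(uniq)$counts), 4L)
})

test_that("complete-deletion removes gap/N columns before comparison", {
  # sequences identical except at a gap-containing column
  aln <- char_aln(c(x = "A-GT", y = "ACGT"))
  h <- collapse_haplotypes(aln, site_policy = "complete")
  expect_equal(length(h$counts), 1L)
  expect_equal(h$n_retained_sites, 3L)
  h2 <- collapse_haplotypes(aln, site_policy = "strict")
  expect_equal(length(h2$counts), 2L)
  # all columns removed -> degenerate input
  bad <- char_aln(c(x = "-N", y = "A-"))
  expect_error(collapse_haplotypes(bad), "degenerate")
})

test_that("collapsing is a partition matching brute-force comparison", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:20, 1L)
    d <- simulate_dataset(demography_constant(3, n, L = 60),
                          seed = 100 + rep)
    m <- toupper(as.character(as.matrix(d$alignment)))
    h <- collapse_haplotypes(m)
    # labels cover all ids
    expect_setequal(names(h$labels), rownames(m))
    expect_equal(sum(h$counts), n)
    # brute force: all-pairs identity
    key <- apply(m, 1L, paste, collapse = "")
    expect_equal(length(h$counts), length(unique(key)))
    same_label <- outer(h$labels, h$labels, "==")
    same_seq <- outer(key, key, "==")
    expect_true(all(same_label == same_seq))
  }
})

test_that("haplotype tables parse, validate and round-trip", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("locality\thaplogroup\tn\thaplotypes",
               "LocA\tG1\t5\tH01(2), H03(2), H06",
               "LocB\tG1\t3\tH01, H02(2)",
               "LocC\tG2\t4\tH07(4)"), tf)
  ht <- parse_haplotype_table(tf)
  expect_s3_class(ht, "haplotype_table")
  expect_equal(ht$grand_total, 12L)
  expect_equal(unname(ht$locality_totals), c(5L, 3L, 4L))
  expect_equal(sort(ht$haplotype_labels),
               c("H01", "H02", "H03", "H06", "H07"))
  cnt <- haplotype_counts(ht, "G1")
  expect_equal(unname(cnt[c("H01", "H02", "H03", "H06")]),
               c(3L, 2L, 2L, 1L))

  # serialize -> parse is idempotent
  tf2 <- tempfile(fileext = ".tsv")
  write_haplotype_table(ht, tf2)
  ht2 <- parse_haplotype_table(tf2)
  expect_equal(ht2$rows$n, ht$rows$n)
  expect_equal(ht2$counts, ht$counts)

  # declared n inconsistent with counts -> error naming the locality
  writeLines(c("locality\thaplogroup\tn\thaplotypes",
               "LocD\tG1\t9\tH01(2), H02"), tf)
  expect_error(parse_haplotype_table(tf), "LocD")
  ht3 <- parse_haplotype_table(tf, on_mismatch = "declared")
  expect_equal(ht3$grand_total, 9L)
  expect_true(ht3$rows$flagged)
  ht4 <- parse_haplotype_table(tf, on_mismatch = "tokens")
  expect_equal(ht4$grand_total, 3L)

  writeLines(c("locality\thaplogroup\tn\thaplotypes",
               "LocE\tG1\t2\tH01(2x)"), tf)
  expect_error(parse_haplotype_table(tf), "malformed")
})

test_that("subset_by_group restricts tables and alignments", {
  ht <- parse_haplotype_table(freq_table_path(), on_mismatch = "declared")
  qlm <- subset_by_group(ht, "QLM")
  expect_true(all(qlm$rows$haplogroup == "QLM"))
  expect_error(subset_by_group(ht, "XXX"), "lookup error")
  # group totals sum to grand total for any partition
  groups <- unique(ht$rows$haplogroup)
  expect_equal(sum(vapply(groups,
                          function(g) subset_by_group(ht, g)$grand_total,
                          numeric(1))),
               ht$grand_total)

  d <- simulate_dataset(demography_split(3, 0.5, 1, 4, 3, L = 50),
                        seed = 9)
  s1 <- subset_by_group(d$alignment, "POP1", d$map)
  expect_equal(nrow(s1), 4L)
  expect_error(subset_by_group(d$alignment, "POP9", d$map),
               "lookup error")
  # restriction to a group covering all rows is the identity
  map_all <- d$map
  map_all$haplogroup <- "ALL"
  expect_equal(nrow(subset_by_group(d$alignment, "ALL", map_all)), 7L)
})

test_that("population maps validate locality-haplogroup consistency", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("id\tlocality\thaplogroup",
               "s1\tA\tG1", "s2\tA\tG2"), tf)
  expect_error(read_population_map(tf), "more than one haplogroup")
  writeLines(c("id\tlocality\thaplogroup",
               "s1\tA\tG1", "s2\tB\tG2"), tf)
  m <- read_population_map(tf)
  expect_equal(m$haplogroup, c("G1", "G2"))
})
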