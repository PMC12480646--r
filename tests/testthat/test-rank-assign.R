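test_that("percent identity matches hand-worked cases", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  expect_equal(percent_identity("ACGTACGT", "ACGTCGT"), 87.5)  # one deletion
  expect_equal(percent_identity("acgt", "ACGT"), 100)          # case-insensitive
  expect_error(percent_identity("", "ACGT"), "non-empty")
  expect_error(percent_identity("ACGT", "ACXT"), "non-nucleotide")
})

test_that("percent identity matches brute-force alignment enumeration", {
  set.seed(19)
  for (i in 1:40) {
    q <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE),
               collapse = "")
    r <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE),
               collapse = "")
    expect_equal(percent_identity(q, r), brute_identity(q, r),
                 info = paste(q, "vs", r))
  }
})

test_that("ranks follow the optimized similarity thresholds with inclusive boundaries", {
  expect_equal(assign_rank(97.8), "species")
  expect_equal(assign_rank(96.5), "genus")     # 96.2 <= 96.5 < 97.8
  expect_equal(assign_rank(80.0), "unclassified")

  # monotone: higher identity never yields a shallower rank
  depth <- c(unclassified = 0, class = 1, order = 2, family = 3,
             genus = 4, species = 5)
  ids <- sort(stats::runif(200, 0, 100))
  expect_true(all(diff(depth[assign_rank(ids)]) >= 0))

  expect_error(assign_rank(101), "\\[0, 100\\]")
  expect_error(rank_thresholds(species = 90, genus = 95), "decreasing")
})

test_that("classify_sequences picks best hits, breaks ties, truncates lineage", {
  refs <- c(refA = "ACGTACGTACGTACGTACGT",
            refB = "TTGGCCAATTGGCCAATTGG")
  lineage <- data.frame(ref_id = c("refA", "refB"),
                        class = "Bivalvia", order = c("Unionida", "Myida"),
                        family = c("Unionidae", "Dreissenidae"),
                        genus = c("Lasmigona", "Dreissena"),
                        species = c("Lasmigona costata", "Dreissena polymorpha"))

  # exact match carries its full weight at species rank
  info <- data.frame(query_id = "q1", sample_id = "S1", primer_id = "P01",
                     weight = 500)
  out <- classify_sequences(c(q1 = refs[["refA"]]), info, refs, lineage)
  expect_equal(out$taxon, "Lasmigona costata")
  expect_equal(out$rank, "species")
  expect_equal(out$reads, 500L)

  # equidistant query: lexicographically first reference id wins
  base40 <- paste(rep("ACGT", 10), collapse = "")
  refs2 <- c(refZ = paste0(substr(base40, 1, 39), "A"),
             refY = paste0(substr(base40, 1, 39), "C"))
  lin2 <- data.frame(ref_id = c("refZ", "refY"), class = "Bivalvia",
                     order = "Myida", family = "Dreissenidae",
                     genus = c("GenusZ", "GenusY"),
                     species = c("Species Z", "Species Y"))
  q <- c(q1 = base40)                   # 39/40 = 97.5% to both -> genus
  out <- classify_sequences(q, info, refs2, lin2)
  expect_equal(out$rank, "genus")
  expect_equal(out$taxon, "GenusY")     # refY sorts before refZ

  # ~90% identity resolves at family rank with the family name as taxon
  ref60 <- paste(rep("ACGT", 15), collapse = "")
  s <- strsplit(ref60, "")[[1]]
  s[c(2, 10, 18, 26, 34, 42)] <- "A"    # six C->A flips: 54/60 columns match
  q90 <- paste(s, collapse = "")
  expect_equal(percent_identity(q90, ref60), 90)
  out <- classify_sequences(c(q1 = q90), info, c(refU = ref60),
                            data.frame(ref_id = "refU", class = "Bivalvia",
                                       order = "Unionida", family = "Unionidae",
                                       genus = "Lasmigona",
                                       species = "Lasmigona costata"))
  expect_equal(out$rank, "family")
  expect_equal(out$taxon, "Unionidae")

  expect_error(classify_sequences(q, info, character(0), lineage), "empty reference")
})

test_that("classification conserves weight and aggregates tally rows", {
  set.seed(5)
  refs <- read_fasta(system.file("extdata", "toy_references.fasta",
                                 package = "ednadetect"))
  lineage <- read_lineage_table(system.file("extdata", "toy_lineage.tsv",
                                            package = "ednadetect"))
  qnames <- sprintf("q%d", 1:6)
  queries <- vapply(qnames, function(x) {
    base <- refs[[sample(length(refs), 1)]]
    s <- strsplit(base, "")[[1]]
    flip <- sample(length(s), sample(0:5, 1))
    s[flip] <- sample(c("A", "C", "G", "T"), length(flip), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  info <- data.frame(query_id = qnames,
                     sample_id = sample(c("S1", "S2"), 6, replace = TRUE),
                     primer_id = "P01",
                     weight = sample(10:500, 6))
  out <- classify_sequences(queries, info, refs, lineage)
  expect_equal(sum(out$reads), sum(info$weight))
  expect_false(anyDuplicated(paste(out$sample_id, out$primer_id, out$taxon,
                                   out$rank)) > 0)
})
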