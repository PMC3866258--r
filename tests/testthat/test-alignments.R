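test_that("aligned FASTA parses, validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1_ECOLI/1-10", "ACDEFGHIKL",
               ">p2_THET8/3-12", "ACDEFG-IKL",
               ">p3_HUMAN/1-10", "XCDEFGHIKB"), f)
  aln <- read_alignment(f, "fasta", "protein")
  expect_equal(nrow(aln$seq_mat), 3L)
  expect_equal(ncol(aln$seq_mat), 10L)
  expect_equal(aln$organisms, c("ECOLI", "THET8", "HUMAN"))
  # out-of-alphabet codes become gaps
  expect_equal(aln$seq_mat[3, c(1, 10)], c("-", "-"))

  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  back <- read_alignment(out, "fasta", "protein")
  expect_identical(back$seq_mat, aln$seq_mat)
  expect_identical(back$ids, aln$ids)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEFGHIKL", ">b", "ACDEFGHIK"), bad)
  expect_error(read_alignment(bad, "fasta", "protein"), "unequal")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_alignment(empty, "fasta", "protein"), "empty")
})

test_that("RNA sequences are normalized (T -> U, case folding)", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1_ECOLI", "acgtu"), f)
  aln <- read_alignment(f, "fasta", "rna")
  expect_equal(paste0(aln$seq_mat[1, ], collapse = ""), "ACGUU")
})

test_that("Stockholm files parse with #=GS OS organism tags and wrapping", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c(
    "# STOCKHOLM 1.0",
    "#=GS RL18_THETH/1-5  OS Thermus thermophilus",
    "#=GS RL18_ECOLI/1-5  OS Escherichia coli",
    "RL18_THETH/1-5   AC-",
    "RL18_ECOLI/1-5   GG-",
    "seq3_YEAST/1-5   AAA",
    "seq4_HUMAN/1-5   CCC",
    "",
    "RL18_THETH/1-5   DE",
    "RL18_ECOLI/1-5   FG",
    "seq3_YEAST/1-5   HH",
    "seq4_HUMAN/1-5   KK",
    "#=GC SS_cons     .....",
    "//"), f)
  aln <- read_alignment(f, "stockholm", "protein")
  expect_equal(length(aln$ids), 4L)
  expect_equal(ncol(aln$seq_mat), 5L)
  # wrapped blocks are concatenated per row
  expect_equal(paste0(aln$seq_mat[1, ], collapse = ""), "AC-DE")
  # OS annotation wins over the mnemonic token where present
  expect_equal(aln$organisms[1:2],
               c("Thermus thermophilus", "Escherichia coli"))
  expect_equal(aln$organisms[3:4], c("YEAST", "HUMAN"))
})

test_that("degapping removes reference-gap columns and is idempotent", {
  p <- alignment(c("ref_A", "o_B"), c("A-CD", "AEC-"), "protein",
                 organisms = c("A", "B"))
  d <- degap_to_reference(p)
  expect_equal(paste0(d$seq_mat[1, ], collapse = ""), "ACD")
  expect_equal(paste0(d$seq_mat[2, ], collapse = ""), "AC-")

  nogap <- alignment("x_A", "ACDE", "protein", organisms = "A")
  expect_identical(degap_to_reference(nogap)$seq_mat, nogap$seq_mat)

  # random alignment with 8 reference gaps vs an independent column filter
  set.seed(7)
  cols <- 40L
  ref <- sample(AA <- c("A", "C", "D", "E", "G"), cols, replace = TRUE)
  gap_cols <- sample(cols, 8)
  ref[gap_cols] <- "-"
  rows <- c(paste0(ref, collapse = ""),
            replicate(5, paste0(sample(c(AA, "-"), cols, replace = TRUE),
                                collapse = "")))
  aln <- alignment(sprintf("s%d_O%d", 1:6, 1:6), rows, "protein",
                   organisms = sprintf("O%d", 1:6))
  d <- degap_to_reference(aln)
  keep <- strsplit(rows[1], "")[[1]] != "-"
  expect_equal(ncol(d$seq_mat), 32L)
  for (k in 1:6) {
    expect_equal(d$seq_mat[k, ], strsplit(rows[k], "")[[1]][keep])
  }
  expect_false(any(d$seq_mat[1, ] == "-"))
  expect_identical(degap_to_reference(d), d)

  allgap <- alignment(c("a_X", "b_Y"), c("---", "ACD"), "protein",
                      organisms = c("X", "Y"))
  expect_error(degap_to_reference(allgap), "all gaps")
})

test_that("organism pairing intersects tags and keeps first occurrences", {
  mk <- function(kind, orgs) {
    alphabet <- if (kind == "protein") "A" else "G"
    alignment(sprintf("s%d_%s", seq_along(orgs), orgs),
              rep(alphabet, length(orgs)), kind, organisms = orgs)
  }
  pr <- pair_by_organism(mk("protein", c("ECOLI", "THET8", "HUMAN")),
                         mk("rna", c("ECOLI", "THET8", "YEAST")))
  expect_equal(nrow(pr$pairs), 2L)
  expect_equal(pr$pairs[1, ], c(protein_row = 1L, rna_row = 1L))

  orgs5 <- sprintf("ORG%d", 1:5)
  pr5 <- pair_by_organism(mk("protein", orgs5), mk("rna", orgs5))
  expect_equal(nrow(pr5$pairs), 5L)

  # duplicate organisms: the first occurrence is paired, the rest dropped
  pdup <- mk("protein", c("ECOLI", "THET8", "XX", "THET8", "YY"))
  rdup <- mk("rna", c("ECOLI", "THET8"))
  prd <- pair_by_organism(pdup, rdup)
  expect_equal(sort(prd$pairs[, "protein_row"]), c(1L, 2L))
  expect_false(4L %in% prd$pairs[, "protein_row"])

  expect_error(pair_by_organism(mk("protein", c("A1", "A2")),
                                mk("rna", c("B1", "B2"))),
               "no organisms in common")

  # pair count bound and tag consistency
  prx <- pair_by_organism(mk("protein", c("O1", "O2", "O3", "O4")),
                          mk("rna", c("O2", "O4", "O9")))
  expect_lte(nrow(prx$pairs), 3L)
  # the reference rows (pair 1) are force-paired; all other pairs must
  # share an organism tag
  tags_p <- prx$protein$organisms[prx$pairs[-1, 1]]
  tags_r <- prx$rna$organisms[prx$pairs[-1, 2]]
  expect_identical(tags_p, tags_r)
})
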