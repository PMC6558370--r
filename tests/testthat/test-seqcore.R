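test_that("read_assembly normalizes case, order and ambiguity codes", {
  fa <- write_temp_fasta(list(s1 = "acgtN"))
  ss <- read_assembly(fa)
  expect_equal(names(ss), "s1")
  expect_equal(as.character(ss[[1]]), "ACGTN")
  expect_equal(Biostrings::width(ss), 5L)

  fa2 <- write_temp_fasta(list(s1 = "ACGT", s2 = "GGCC"))
  ss2 <- read_assembly(fa2)
  expect_equal(names(ss2), c("s1", "s2"))

  # ambiguity codes other than N map to N, position by position
  fa3 <- write_temp_fasta(list(s1 = "ARYT"))
  expect_warning(ss3 <- read_assembly(fa3), "ambiguity")
  chars <- strsplit("ARYT", "")[[1]]
  expected <- paste(ifelse(chars %in% c("A", "C", "G", "T", "N"), chars, "N"),
                    collapse = "")
  expect_equal(as.character(ss3[[1]]), expected)

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_assembly(empty))
  fa4 <- write_temp_fasta(list(a = "ACGT", a = "GGGG"))
  expect_error(read_assembly(fa4), "duplicate")
})

test_that("detect_gaps reports maximal N runs at or above the threshold", {
  s <- random_dna_str(200, seed = 1)
  expect_equal(nrow(detect_gaps(s)), 0L)

  s2 <- paste0(substr(s, 1, 100), strrep("N", 50), substr(s, 101, 150))
  g <- detect_gaps(s2, min_run = 10)
  expect_equal(g, data.frame(start = 101L, end = 150L, length = 50L))

  s3 <- paste0(substr(s, 1, 100), strrep("N", 5), substr(s, 101, 200))
  expect_equal(nrow(detect_gaps(s3, min_run = 10)), 0L)
})

test_that("detect_gaps partitions N positions (property)", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 400
    ch <- sample(c("A", "C", "G", "T", "N"), n, TRUE,
                 prob = c(rep(0.2, 4), 0.2))
    s <- paste(ch, collapse = "")
    g <- detect_gaps(s, min_run = 4)
    in_gap <- rep(FALSE, n)
    for (i in seq_len(nrow(g))) in_gap[g$start[i]:g$end[i]] <- TRUE
    # every reported position is N
    expect_true(all(ch[in_gap] == "N"))
    # every N outside a reported gap lies in a run shorter than min_run
    runs <- rle(ch == "N")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    long_n <- which(runs$values & runs$lengths >= 4)
    for (k in long_n) expect_true(all(in_gap[starts[k]:ends[k]]))
    short_n <- which(runs$values & runs$lengths < 4)
    for (k in short_n) expect_true(all(!in_gap[starts[k]:ends[k]]))
  }
})

test_that("region_length uses the 1-based closed convention", {
  expect_equal(region_length(3052198, 3052512), 315L)
  expect_equal(region_length(7, 7), 1L)
  expect_equal(region_length(1, 100), 100L)
  expect_error(region_length(10, 9), "end < start")
})

test_that("region_length is additive over adjacent intervals", {
  set.seed(3)
  for (rep in 1:20) {
    a <- sample.int(1000, 1)
    b <- a + sample.int(100, 1) - 1
    c_ <- b + sample.int(100, 1)
    expect_equal(region_length(a, b) + region_length(b + 1, c_),
                 region_length(a, c_))
  }
})

test_that("translate_cds splices, translates and flags", {
  expect_equal(as.character(translate_cds(cbind(1, 9), "+", "ATGAAATAA")), "MK*")

  # two exons with an intervening intron; oracle: splice then translate
  exon1 <- "ATGAA"
  intron <- "GTAAGTACAG"
  exon2 <- "ACGTTAA"
  s <- paste0(exon1, intron, exon2)
  spliced <- paste0(exon1, exon2)
  oracle <- as.character(Biostrings::translate(Biostrings::DNAString(spliced)))
  got <- translate_cds(rbind(c(1, 5), c(16, 22)), "+", s)
  expect_equal(as.character(got), oracle)
  expect_equal(as.character(got), "MKR*")

  # minus strand: reverse complement of the forward gene
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  got_rc <- translate_cds(rbind(c(1, 7), c(18, 22)), "-", rc)
  expect_equal(as.character(got_rc), "MKR*")

  # exon across an N gap -> incomplete flag
  s_gap <- paste0("ATG", strrep("N", 12), "AAATAA")
  gaps <- detect_gaps(s_gap, min_run = 10)
  got_gap <- translate_cds(cbind(1, 21), "+", s_gap, gaps = gaps)
  expect_true(attr(got_gap, "incomplete"))

  expect_error(translate_cds(cbind(1, 50), "+", "ATGAAA"), "bounds")
})

test_that("stitch_scaffolds chains exact terminal overlaps", {
  set.seed(11)
  a <- random_dna_str(500)
  b <- paste0(substr(a, 451, 500), random_dna_str(300))
  lay <- stitch_scaffolds(c(A = a, B = b), min_overlap = 50)
  expect_equal(lay$chains[[1]]$scaffold, c("A", "B"))
  expect_equal(lay$merged_lengths, 500L + 350L - 50L)

  # short middle scaffold bridging two larger ones
  left <- random_dna_str(800)
  mid <- paste0(substr(left, 701, 800), random_dna_str(120), "")
  right <- paste0(substr(mid, 121, 220), random_dna_str(500))
  lay2 <- stitch_scaffolds(c(right = right, left = left, mid = mid),
                           min_overlap = 100)
  expect_equal(lay2$chains[[1]]$scaffold, c("left", "mid", "right"))
  expect_equal(merge_chain(lay2, 1),
               paste0(left, substr(mid, 101, 220), substr(right, 101, nchar(right))))

  # no qualifying overlaps -> everything unplaced
  lay3 <- stitch_scaffolds(c(x = random_dna_str(200), y = random_dna_str(200)),
                           min_overlap = 100)
  expect_equal(length(lay3$chains), 0L)
  expect_setequal(lay3$unplaced, c("x", "y"))

  # one end matching two partners equally -> error listing candidates
  core <- random_dna_str(100)
  amb <- c(p = paste0(random_dna_str(150), core),
           q = paste0(core, random_dna_str(80)),
           r = paste0(core, random_dna_str(90)))
  expect_error(stitch_scaffolds(amb, min_overlap = 100), "ambiguous")
})

test_that("AGP output tiles each chain exactly", {
  set.seed(12)
  a <- random_dna_str(400)
  b <- paste0(substr(a, 301, 400), random_dna_str(250))
  lay <- stitch_scaffolds(c(A = a, B = b), min_overlap = 100)
  agp <- tempfile(fileext = ".agp")
  write_agp(lay, agp)
  lines <- readLines(agp)
  expect_equal(lines[1], "##agp-version\t2.1")
  rows <- read.table(text = lines[-1], sep = "\t", stringsAsFactors = FALSE)
  ch <- rows[rows$V1 == "chain1", ]
  expect_equal(ch$V2[1], 1L)
  expect_equal(ch$V3[nrow(ch)], lay$merged_lengths[1])
  # parts tile without gaps or overlaps
  expect_true(all(ch$V2[-1] == head(ch$V3, -1) + 1L))
})

test_that("GFF3 written by the package re-reads to the same annotation", {
  map <- small_map()
  gf <- tempfile(fileext = ".gff3")
  write_gff3(map, gf)
  m2 <- read_gff3(gf, label = map$label)
  cols <- c("name", "type", "start", "end", "strand", "n_exons", "functionality")
  expect_equal(locus_map_table(m2)[cols], locus_map_table(map)[cols])
})
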