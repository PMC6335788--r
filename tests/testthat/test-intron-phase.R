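test_that("a single exon maps residues to codon-sized genomic intervals", {
  m <- gene_model("g1", data.frame(start = 101, end = 400))
  map <- build_cds_map(m)
  expect_equal(cds_to_genomic(map, 1:3), 101:103)
  expect_equal(cds_to_genomic(map, protein_to_cds(1)[1, ]), 101:103)
  expect_equal(genomic_to_cds(map, 400), 300L)
  expect_equal(nrow(locate_introns(m)), 0L)
})

test_that("phase follows the mod-3 rule at the first junction", {
  # first exon carrying 10, 11 and 9 CDS nt respectively
  for (case in list(c(10, 1), c(11, 2), c(9, 0))) {
    m <- gene_model("g", data.frame(start = c(1, 200),
                                    end = c(case[1], 200 + 60 - case[1] - 1)))
    ir <- locate_introns(m)
    expect_equal(ir$phase, case[2])
    expect_equal(ir$cds_offset, case[1])
  }
})

test_that("phase arithmetic matches a nucleotide-level splicing simulation", {
  set.seed(42)
  for (i in 1:30) {
    cs <- random_gene_case(i)
    gm <- cs$gene
    ir <- locate_introns(gm$model)
    # splice the genomic sequence with the exon coordinates and retranslate
    map <- build_cds_map(gm$model)
    chrom_local <- cds_to_genomic(map, seq_len(nchar(gm$cds)))
    offset <- min(gm$model$exons$start) - 1L
    chars <- strsplit(gm$genomic_sequence, "")[[1]]
    spliced <- chars[chrom_local - offset]
    if (gm$model$strand == "-") {
      # minus-strand CDS reads the complement of the forward bases
      spliced <- chartr("ACGT", "TGCA", spliced)
    }
    expect_equal(paste(spliced, collapse = ""), gm$cds)
    expect_equal(translate_cds(gm$cds), cs$protein$sequence)
    # phases are cumulative exon lengths mod 3
    lens <- gm$model$exons$end - gm$model$exons$start + 1L
    expect_equal(ir$phase, cumsum(lens)[seq_len(nrow(ir))] %% 3L)
    expect_equal(sum(lens) %% 3L, 0L)
  }
})

test_that("coordinate round trips are identities on both strands", {
  for (strand in c("+", "-")) {
    for (i in 1:25) {
      cs <- random_gene_case(i + ifelse(strand == "+", 1000L, 2000L))
      m <- cs$gene$model
      map <- build_cds_map(m)
      L <- sum(m$exons$end - m$exons$start + 1L)
      expect_equal(genomic_to_cds(map, cds_to_genomic(map, seq_len(L))),
                   seq_len(L))
    }
  }
})

test_that("synthetic gene models round-trip their planted intron records", {
  for (i in 1:40) {
    cs <- random_gene_case(i + 3000L)
    got <- locate_introns(cs$gene$model)
    got <- annotate_domain_positions(got, cs$protein$annotation)
    expect_equal(got, cs$gene$introns, info = paste("case", i))
  }
})

test_that("domain-position annotation places the canonical pattern introns", {
  spec <- random_domain_spec(7, max_flank = 30L)
  p <- make_domain_protein(spec)
  # P0 intron after hinge position -5
  gm_a <- make_gene_model(p$sequence, intron_plan(-5, 0), seed = 1,
                          annotation = p$annotation)
  expect_equal(gm_a$introns$region, "hinge")
  expect_equal(gm_a$introns$domain_pos, -5L)
  expect_equal(gm_a$introns$phase, 0L)
  # P2 intron inside the codon of basic position -20
  gm_c <- make_gene_model(p$sequence, intron_plan(-20, 2), seed = 1,
                          annotation = p$annotation)
  expect_equal(gm_c$introns$region, "basic")
  expect_equal(gm_c$introns$domain_pos, -20L)
  # far-downstream intron is outside the window
  gm_o <- make_gene_model(p$sequence,
                          intron_plan(nchar(p$sequence) - 2L, 0),
                          seed = 1, annotation = p$annotation)
  expect_equal(gm_o$introns$region, "outside")
  expect_true(is.na(gm_o$introns$domain_pos))
})

test_that("classify_pattern implements the four canonical classes strictly", {
  rec <- function(region, pos, phase) {
    data.frame(index = seq_along(region),
               cds_offset = rep(0L, length(region)), phase = phase,
               protein_pos = rep(0L, length(region)), domain_pos = pos,
               region = region)
  }
  expect_equal(classify_pattern(rec(character(0), integer(0), integer(0))),
               "d")
  expect_equal(classify_pattern(rec("outside", NA, 1L)), "d")
  expect_equal(classify_pattern(rec("hinge", -5L, 0L)), "a")
  expect_equal(classify_pattern(rec(c("basic", "hinge"), c(-14L, -3L),
                                    c(0L, 0L))), "b")
  expect_equal(classify_pattern(rec("basic", -20L, 2L)), "c")
  expect_equal(classify_pattern(rec("basic", -20L, 1L)), "other")
  expect_equal(classify_pattern(rec("hinge", -4L, 0L)), "other")
  expect_equal(classify_pattern(rec(c("basic", "basic"), c(-20L, -12L),
                                    c(0L, 0L))), "other")
})

test_that("invalid gene models are rejected", {
  expect_error(gene_model("g", data.frame(start = c(1, 5), end = c(10, 20))),
               "overlap")
  expect_error(gene_model("g", data.frame(start = 1, end = 10)),
               "divisible")
  p <- make_domain_protein(random_domain_spec(3))
  expect_error(make_gene_model(p$sequence,
                               intron_plan(nchar(p$sequence), 0),
                               annotation = p$annotation),
               "beyond")
})
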