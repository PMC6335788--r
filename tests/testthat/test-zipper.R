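test_that("register assignment anchors the first leucine at d of heptad 1", {
  expect_error(assign_register(zipper = ""), "empty|invalid")
  # leucines every 7 residues from +1 all land on d
  z <- strrep("LAAAAAA", 4)
  reg <- assign_register(zipper = z)
  expect_true(all(reg$slot[reg$residue == "L"] == "d"))
  expect_equal(max(reg$heptad), ceiling(nchar(z) / 7) + 1L)
  expect_equal(sum(reg$slot == "d" & reg$residue == "L"), 4L)
  # heptad 1 holds only d-g
  h1 <- reg[reg$heptad == 1L, ]
  expect_equal(h1$slot, c("d", "e", "f", "g"))
})

test_that("a 23-residue zipper spans heptads 1..4 with a partial heptad 4", {
  reg <- assign_register(zipper = paste(rep("L", 23), collapse = ""))
  expect_equal(sort(unique(reg$heptad)), 1:4)
  expect_equal(reg$slot[reg$heptad == 4L], c("a", "b", "c", "d", "e"))
})

test_that("register assignment is idempotent over the zipper span", {
  spec <- random_domain_spec(31)
  p <- make_domain_protein(spec)
  r1 <- assign_register(p$annotation, p$sequence)
  r2 <- assign_register(zipper = paste(spec$zipper_heptads, collapse = ""),
                        protein_id = p$annotation$protein_id)
  expect_equal(r1, r2)
})

test_that("composition tables recover planted residue multisets exactly", {
  # one register, all leucine
  reg <- assign_register(zipper = strrep("L", 21))
  comp <- composition_by_position(reg)
  for (p in c("a", "d", "e", "g")) {
    expect_equal(comp[[p]]$freq, c(L = 1.0))
  }
  # 50 zippers: a-slots 60% N / 40% K by construction
  regs <- lapply(1:50, function(i) {
    a_res <- if (i <= 30) "N" else "K"
    # slots from +1: d e f g a b c -> a is the 5th residue
    assign_register(zipper = paste0("LQEK", a_res, "AS"),
                    protein_id = paste0("z", i))
  })
  comp <- composition_by_position(regs)
  expect_equal(comp$a$freq[["N"]], 0.6, tolerance = 1e-12)
  expect_equal(comp$a$freq[["K"]], 0.4, tolerance = 1e-12)
  expect_equal(comp$a$n, 50L)
  expect_equal(sum(comp$d$freq), 1, tolerance = 1e-9)
  # X is excluded from denominators
  regx <- assign_register(zipper = "LQEKXAS")
  compx <- composition_by_position(list(regx))
  expect_equal(compx$a$n, 0L)
})

test_that("the Asn-at-a histogram counts per heptad", {
  regs <- lapply(1:10, function(i) {
    # heptad 2 a-slot at +5; heptad 3 a-slot at +12
    a2 <- if (i <= 7) "N" else "Q"
    assign_register(zipper = paste0("LQEK", a2, "ASLQEKQAS"),
                    protein_id = paste0("z", i))
  })
  h <- asn_a_by_heptad(regs)
  expect_equal(h$pct[h$heptad == 2L], 70)
  expect_equal(h$pct[h$heptad == 3L], 0)
  expect_equal(h$n_total, c(10L, 10L))
  # no Asn anywhere: all zeros
  h0 <- asn_a_by_heptad(assign_register(zipper = strrep("LQEKQAS", 3)))
  expect_true(all(h0$pct == 0))
})

test_that("g<->e' pairs follow the electrostatic charge rule", {
  # g of heptad 1 at +4, e of heptad 2 at +9
  mk <- function(g, e) assign_register(zipper = paste0("LQA", g, "LEQL", e, "E"))
  expect_equal(classify_ge_pairs(mk("K", "E"))$category,
               "attractive_plus_minus")
  expect_equal(classify_ge_pairs(mk("E", "R"))$category,
               "attractive_minus_plus")
  expect_equal(classify_ge_pairs(mk("R", "K"))$category, "basic_repulsive")
  expect_equal(classify_ge_pairs(mk("D", "E"))$category, "acidic_repulsive")
  expect_equal(classify_ge_pairs(mk("A", "S"))$category, "uncharged")
  # histidine is uncharged
  expect_equal(classify_ge_pairs(mk("H", "E"))$category, "uncharged")
  # fewer than two heptads: no pairs
  expect_equal(nrow(classify_ge_pairs(assign_register(zipper = "LQAK"))), 0L)
})

test_that("aggregated g<->e' categories partition all pairs", {
  regs <- lapply(1:20, function(i) {
    spec <- random_domain_spec(i + 500L, n_heptads_range = c(3L, 6L))
    p <- make_domain_protein(spec)
    assign_register(p$annotation, p$sequence,
                    protein_id = paste0("p", i))
  })
  agg <- aggregate_ge(regs, per_heptad = TRUE)
  n_pairs <- sum(vapply(regs, function(r) nrow(classify_ge_pairs(r)),
                        integer(1)))
  expect_equal(sum(agg$count), n_pairs)
  per_h <- tapply(agg$freq, agg$heptad, sum)
  expect_true(all(abs(per_h[tapply(agg$count, agg$heptad, sum) > 0] - 1)
                  < 1e-9))
  agg_all <- aggregate_ge(regs, per_heptad = FALSE)
  expect_equal(sum(agg_all$freq), 1, tolerance = 1e-9)
})

test_that("heptad alignment tables round-trip through the TSV reader", {
  tab <- data.frame(protein_id = c("p1", "p2"),
                    h1_d = c("L", "L"), h1_e = c("Q", "E"),
                    h1_g = c("K", "D"), h2_a = c("N", "-"),
                    h2_e = c("E", "E"), check.names = FALSE)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  regs <- read_heptad_alignment(f)
  expect_length(regs, 2L)
  expect_equal(regs[[1]]$residue[regs[[1]]$slot == "a"], "N")
  expect_equal(nrow(regs[[2]][regs[[2]]$slot == "a", ]), 0L)
  pairs <- classify_ge_pairs(regs[[1]])
  expect_equal(pairs$category, "attractive_plus_minus")
  h <- asn_a_by_heptad(regs)
  expect_equal(h$pct[h$heptad == 2L], 100)
})
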