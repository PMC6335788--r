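# Independent oracles used across the suite. These deliberately use naive
# enumeration, separate from the package's implementations.

# Brute-force bZIP anchor scan: test every index of the sequence.
brute_scan_anchors <- function(seq, relaxed = FALSE, min_heptads = 2L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  allowed <- c("R", "K", if (relaxed) "I")
  hits <- integer(0)
  for (i in seq_len(n)) {
    last <- i + 18L + 7L * (min_heptads - 1L)
    if (last > n) next
    if (ch[i] != "N") next
    if (!(ch[i + 8L] %in% allowed)) next
    if (!all(ch[i + 18L + 7L * (0:(min_heptads - 1L))] == "L")) next
    hits <- c(hits, i)
  }
  hits
}

# All permutations of a vector, by naive recursion.
perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Naive NG86 site fraction of one codon: loop over positions and
# alternative nucleotides; synonymous changes over non-stop changes.
oracle_site_fraction <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (nt in c("A", "C", "G", "T")) {
      if (nt == ch[pos]) next
      alt <- ch
      alt[pos] <- nt
      alt_aa <- gc[[paste(alt, collapse = "")]]
      if (alt_aa == "*") next
      nonstop <- nonstop + 1
      if (alt_aa == gc[[codon]]) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

# Naive pathway enumeration for a codon pair: average synonymous and
# nonsynonymous step counts over stop-free substitution orderings (all
# orderings if every one passes through a stop).
oracle_pair_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  x <- strsplit(c1, "")[[1]]
  y <- strsplit(c2, "")[[1]]
  dpos <- which(x != y)
  if (length(dpos) == 0L) return(c(sd = 0, nd = 0))
  counts <- list()
  for (perm in perms_of(dpos)) {
    cur <- x
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in perm) {
      nxt <- cur
      nxt[p] <- y[p]
      a1 <- gc[[paste(cur, collapse = "")]]
      a2 <- gc[[paste(nxt, collapse = "")]]
      if (a2 == "*") blocked <- TRUE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    counts[[length(counts) + 1L]] <- c(sd, nd, blocked)
  }
  m <- do.call(rbind, counts)
  ok <- m[, 3] == 0
  use <- if (any(ok)) m[ok, , drop = FALSE] else m
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

# Naive NG86 + Jukes-Cantor on a pair of codon vectors.
oracle_kaks <- function(cds_a, cds_b) {
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  S <- (sum(vapply(ca, oracle_site_fraction, numeric(1))) +
        sum(vapply(cb, oracle_site_fraction, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in which(ca != cb)) {
    d <- oracle_pair_diffs(ca[i], cb[i])
    sd <- sd + d[["sd"]]
    nd <- nd + d[["nd"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd, Nd = nd,
       ks = if (S > 0) jc(sd / S) else NA_real_,
       ka = if (N > 0) jc(nd / N) else NA_real_)
}

# Random sense-codon CDS of a given codon count.
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# A random synthetic gene case: protein with planted domain, an intron
# plan realizing one of the four basic/hinge patterns (plus introns
# outside the domain window), on a random strand.
random_gene_case <- function(seed) {
  set.seed(seed)
  spec <- random_domain_spec(seed + 1L, max_flank = 60L)
  spec$n_flank_left <- max(spec$n_flank_left, 15L)
  spec$n_flank_right <- max(spec$n_flank_right, 15L)
  prot <- make_domain_protein(spec, id = paste0("p", seed))
  n_res <- nchar(prot$sequence)
  pattern <- sample(c("a", "b", "c", "d"), 1L)
  plan_pos <- switch(pattern,
    a = -5L,
    b = c(sample(-25:-10, 1L), sample(-9:-1, 1L)),
    c = -20L,
    d = integer(0))
  plan_phase <- switch(pattern,
    a = 0L, b = c(0L, 0L), c = 2L, d = integer(0))
  if (sample(c(TRUE, FALSE), 1L)) {       # extra intron in the left flank
    plan_pos <- c(3L, plan_pos)
    plan_phase <- c(sample(0:2, 1L), plan_phase)
  }
  if (sample(c(TRUE, FALSE), 1L)) {       # extra intron near the C terminus
    plan_pos <- c(plan_pos, n_res - 3L)
    plan_phase <- c(plan_phase, sample(0:2, 1L))
  }
  gm <- make_gene_model(prot$sequence, intron_plan(plan_pos, plan_phase),
                        seed = seed + 2L, annotation = prot$annotation,
                        strand = sample(c("+", "-"), 1L),
                        gene_start = sample(1:1000, 1L),
                        gene_id = paste0("gene", seed))
  list(protein = prot, gene = gm, pattern = pattern,
       planted_positions = plan_pos, planted_phases = plan_phase)
}
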