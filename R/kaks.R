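# Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction,
# purifying-selection summaries and the binned Ks distribution.
#
# Site-counting convention: at each codon position the synonymous fraction
# is (number of synonymous single-nucleotide changes) / (number of
# non-stop single-nucleotide changes), so per-codon site fractions sum to
# 3 and S + N equals 3 x (number of codons) exactly. Codons differing at
# several positions are resolved by averaging over all substitution
# orderings with equal weight, skipping orderings that pass through a stop
# codon (all orderings are used as a fallback in the degenerate case where
# every one is blocked).

NT <- c("A", "C", "G", "T")

.ng_env <- new.env(parent = emptyenv())

# synonymous site fraction per sense codon (named vector, length 61)
ng_site_fractions <- function() {
  if (!is.null(.ng_env$sites)) return(.ng_env$sites)
  aa <- codon_aa()
  sense <- sense_codons()
  s <- vapply(sense, function(cod) {
    ch <- seq_chars(cod)
    total <- 0
    for (pos in 1:3) {
      syn <- 0L; nonstop <- 0L
      for (nt in setdiff(NT, ch[pos])) {
        alt <- ch; alt[pos] <- nt
        alt_aa <- aa[[paste(alt, collapse = "")]]
        if (alt_aa == "*") next
        nonstop <- nonstop + 1L
        if (alt_aa == aa[[cod]]) syn <- syn + 1L
      }
      total <- total + if (nonstop > 0L) syn / nonstop else 0
    }
    total
  }, numeric(1))
  .ng_env$sites <- s
  s
}

# average (synonymous, nonsynonymous) differences for a codon pair,
# memoized over the 61 x 61 sense-codon grid
ng_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  memo <- .ng_env$diffs
  if (is.null(memo)) {
    memo <- new.env(parent = emptyenv())
    .ng_env$diffs <- memo
  }
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  aa <- codon_aa()
  x <- seq_chars(c1); y <- seq_chars(c2)
  dpos <- which(x != y)
  k <- length(dpos)
  val <- if (k == 0L) c(sd = 0, nd = 0) else {
    perms <- switch(k,
      list(1L),
      list(c(1L, 2L), c(2L, 1L)),
      list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
    walk <- function(order_idx) {
      cur <- x; sd <- 0L; nd <- 0L; blocked <- FALSE
      for (j in order_idx) {
        p <- dpos[j]
        nxt <- cur; nxt[p] <- y[p]
        a1 <- aa[[paste(cur, collapse = "")]]
        a2 <- aa[[paste(nxt, collapse = "")]]
        if (a2 == "*") blocked <- TRUE
        if (a1 == a2) sd <- sd + 1L else nd <- nd + 1L
        cur <- nxt
      }
      c(sd = sd, nd = nd, blocked = as.integer(blocked))
    }
    paths <- vapply(perms, walk, numeric(3))
    ok <- paths["blocked", ] == 0
    use <- if (any(ok)) paths[, ok, drop = FALSE] else paths
    c(sd = mean(use["sd", ]), nd = mean(use["nd", ]))
  }
  memo[[key]] <- val
  val
}

#' Nei-Gojobori Ka/Ks for a codon-aligned CDS pair
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence by the
#' single-change fractions of each codon (averaged over the two
#' sequences), counts synonymous/nonsynonymous differences by equal-weight
#' averaging over substitution pathways, and applies the Jukes-Cantor
#' multiple-hit correction to the proportions pS and pN. Saturation
#' (`pS >= 3/4` or `pN >= 3/4`, where the correction diverges) is flagged
#' and yields an `NA` rate.
#'
#' @param cds_a,cds_b equal-length, codon-aligned, gap-free coding
#'   sequences without internal stop codons
#' @return object of class `kaks_result`: list with `S`, `N` (site counts,
#'   `S + N = 3 *` codons), `Sd`, `Nd` (differences), `pS`, `pN`, `ka`,
#'   `ks`, `ratio` (`NA` when `ks` is 0 or undefined), `saturated_s`,
#'   `saturated_n`, `n_codons`
#' @export
#' @examples
#' kaks_ng86("TTTGATGCC", "TTCGATGCC")$ks   # approximately 1.207
kaks_ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences differ in length", call. = FALSE)
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  aa <- codon_aa()
  if (any(aa[ca] == "*") || any(aa[cb] == "*"))
    stop("internal stop codon", call. = FALSE)
  sites <- ng_site_fractions()
  S_a <- sum(sites[ca]); S_b <- sum(sites[cb])
  S <- (S_a + S_b) / 2
  n_codons <- length(ca)
  N <- 3 * n_codons - S

  diff_idx <- which(ca != cb)
  sd_tot <- 0; nd_tot <- 0
  for (i in diff_idx) {
    d <- ng_pair_diffs(ca[i], cb[i])
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  pS <- if (S > 0) sd_tot / S else 0
  pN <- if (N > 0) nd_tot / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(pS); ka <- jc(pN)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  structure(list(S = S, N = N, Sd = sd_tot, Nd = nd_tot, pS = pS, pN = pN,
                 ka = ka, ks = ks, ratio = ratio,
                 saturated_s = pS >= 0.75, saturated_n = pN >= 0.75,
                 n_codons = n_codons),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "<kaks_result> %d codons  S=%.2f N=%.2f  Sd=%.2f Nd=%.2f  Ka=%s Ks=%s Ka/Ks=%s\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd,
    format(x$ka, digits = 4), format(x$ks, digits = 4),
    format(x$ratio, digits = 4)))
  invisible(x)
}

#' Summarize purifying selection across duplicated pairs
#'
#' @param results list of [kaks_ng86()] results (or a numeric vector of
#'   Ka/Ks ratios)
#' @param cutoff ratio threshold; ratios strictly below it count as
#'   purifying
#' @return list with `n_below`, `n_at_or_above`, `n_undefined` (pairs with
#'   no defined ratio) and `cutoff`
#' @export
purifying_summary <- function(results, cutoff = 0.5) {
  ratios <- if (is.numeric(results)) results
            else vapply(results, function(r) r$ratio, numeric(1))
  list(n_below = sum(!is.na(ratios) & ratios < cutoff),
       n_at_or_above = sum(!is.na(ratios) & ratios >= cutoff),
       n_undefined = sum(is.na(ratios)),
       cutoff = cutoff)
}

#' Binned Ks distribution with peak detection
#'
#' Half-open bins `[k*bin, (k+1)*bin)`; the peak is the bin with the
#' largest count, ties broken toward the lower bin.
#'
#' @param ks numeric vector of finite, non-negative Ks values (`NA`s are
#'   dropped)
#' @param bin bin width
#' @return object of class `ks_histogram`: list with `bin`, `breaks`,
#'   `mid` (bin midpoints), `counts`, `peak_mid` (midpoint of the peak
#'   bin), `n`
#' @export
ks_histogram <- function(ks, bin = 0.05) {
  ks <- ks[!is.na(ks)]
  if (any(ks < 0)) stop("negative Ks value", call. = FALSE)
  if (length(ks) == 0L) stop("no finite Ks values", call. = FALSE)
  idx <- floor(ks / bin)               # half-open [k*bin, (k+1)*bin)
  upper <- max(idx)
  counts <- tabulate(idx + 1L, nbins = upper + 1L)
  mid <- (seq_len(upper + 1L) - 0.5) * bin
  peak <- which.max(counts)            # which.max takes the lowest tie
  structure(list(bin = bin, breaks = seq(0, (upper + 1L) * bin, by = bin),
                 mid = mid, counts = counts, peak_mid = mid[peak],
                 n = length(ks)),
            class = "ks_histogram")
}

#' Local maxima of a Ks histogram
#'
#' Bins whose count is at least that of both neighbours and positive;
#' useful for spotting the ortholog and whole-genome-duplication modes of
#' mixed Ks distributions.
#'
#' @param h a [ks_histogram()]
#' @return data.frame with `mid` and `count` of each local maximum
#' @export
ks_local_maxima <- function(h) {
  stopifnot(inherits(h, "ks_histogram"))
  cnt <- h$counts
  n <- length(cnt)
  left <- c(-Inf, cnt[-n]); right <- c(cnt[-1L], -Inf)
  keep <- cnt > 0 & cnt >= left & cnt >= right
  data.frame(mid = h$mid[keep], count = cnt[keep])
}
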