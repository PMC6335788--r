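# Seed-development expression-profile classification and 2^-ddCt qPCR
# analysis.

PROFILE_LEVELS <- c("not_expressed", "I", "II", "III", "IV")

#' Classify a three-stage FPKM profile
#'
#' Assigns each gene's (DAF20, DAF40, DAF60) FPKM triple to one of five
#' profile classes: `not_expressed` when every stage is below `floor`;
#' `I` — early peak, DAF20 at least `fold` times the later stages;
#' `II` — mid peak, DAF40 at least `fold` times the flanking stages;
#' `III` — mid trough, DAF40 at most `1/fold` of the flanking stages;
#' `IV` — expressed with no such pivot (including high-and-flat profiles).
#' Labels are invariant to uniform rescaling of the triple while all
#' stages stay above the floor.
#'
#' @param fpkm numeric vector of length 3 `(DAF20, DAF40, DAF60)` or a
#'   matrix/data.frame with those three columns (one gene per row)
#' @param floor minimum FPKM to call a gene expressed
#' @param fold fold-change defining a peak or trough
#' @return character vector of labels (one per gene)
#' @export
#' @examples
#' classify_profile(c(10, 2, 1))   # "I"
#' classify_profile(c(20, 18, 22)) # "IV"
classify_profile <- function(fpkm, floor = 1.0, fold = 2.0) {
  m <- if (is.null(dim(fpkm))) matrix(fpkm, ncol = 3L, byrow = TRUE)
       else as.matrix(fpkm)
  stopifnot(ncol(m) == 3L)
  if (any(m < 0)) stop("negative FPKM value", call. = FALSE)
  d20 <- m[, 1L]; d40 <- m[, 2L]; d60 <- m[, 3L]
  out <- rep("IV", nrow(m))
  out[d40 * fold <= pmin(d20, d60)] <- "III"
  out[d40 >= fold * pmax(d20, d60)] <- "II"
  out[d20 >= fold * pmax(d40, d60)] <- "I"
  out[d20 < floor & d40 < floor & d60 < floor] <- "not_expressed"
  out
}

#' Simulate an FPKM matrix and qPCR Ct table with known profile groups
#'
#' Plants the five profile classes with multiplicative log-normal noise
#' (the simplest positive-valued noise for count-derived abundances):
#' group I peaks at DAF20, II at DAF40, III dips at DAF40, IV is high and
#' flat, and `not_expressed` genes sit well below the expression floor.
#' A companion long-format qPCR Ct table (3 replicates per condition, an
#' internal-control gene column, treatment/control conditions at 0/1/5/10
#' h) is simulated for `n_qpcr_genes` genes with planted ddCt effects.
#'
#' @param group_sizes named integer vector over
#'   `not_expressed, I, II, III, IV`
#' @param base_fpkm baseline FPKM of an expressed stage
#' @param fold planted fold-change between peak/trough and baseline
#'   (> 1; well above the classifier's 2-fold rule for clean recovery)
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param seed integer seed
#' @param n_qpcr_genes genes in the simulated Ct table
#' @param qpcr_ddct planted ddCt (treatment minus control) per time point,
#'   recycled over genes; a matrix `n_qpcr_genes x length(times)` plants
#'   per-gene effects
#' @param times treatment time points (hours)
#' @param ct_sd replicate-level Ct standard deviation
#' @return list with `fpkm` (matrix, columns DAF20/DAF40/DAF60), `labels`
#'   (planted truth), `ct` (long data.frame: `gene`, `condition`,
#'   `time_h`, `replicate`, `ct`, `ct_control`) and `control_gene`
#' @export
make_expression_data <- function(group_sizes = c(not_expressed = 5, I = 5,
                                                 II = 5, III = 5, IV = 5),
                                 base_fpkm = 10, fold = 5, noise_cv = 0.1,
                                 seed = 1L, n_qpcr_genes = 4L,
                                 qpcr_ddct = 0, times = c(0, 1, 5, 10),
                                 ct_sd = 0.15) {
  stopifnot(all(group_sizes >= 0), fold > 1, noise_cv >= 0, base_fpkm > 0)
  stopifnot(all(PROFILE_LEVELS %in% names(group_sizes)))
  group_sizes <- group_sizes[PROFILE_LEVELS]

  hi <- base_fpkm * fold
  lo <- 0.1                       # mean FPKM of silent genes, << floor
  means <- rbind(not_expressed = c(lo, lo, lo),
                 I = c(hi, base_fpkm, base_fpkm),
                 II = c(base_fpkm, hi, base_fpkm),
                 III = c(hi, base_fpkm, hi),
                 IV = c(hi, hi, hi))
  labels <- rep(PROFILE_LEVELS, times = group_sizes)
  sdlog <- sqrt(log(1 + noise_cv^2))

  with_seed(seed, {
    mu <- means[labels, , drop = FALSE]
    noise <- matrix(stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog), nrow = nrow(mu))
    fpkm <- mu * noise
    colnames(fpkm) <- c("DAF20", "DAF40", "DAF60")
    rownames(fpkm) <- if (nrow(fpkm) > 0L)
      paste0("gene", seq_len(nrow(fpkm))) else NULL

    ct <- simulate_qpcr_ct_(n_qpcr_genes, qpcr_ddct, times, ct_sd)
    list(fpkm = fpkm, labels = labels, ct = ct,
         control_gene = "actin_control")
  })
}

# Ct simulation under the current RNG state. Control-gene Ct ~ 20, target
# baseline dCt = 5; treatment dCt at each time adds the planted ddCt.
simulate_qpcr_ct_ <- function(n_genes, ddct, times, ct_sd) {
  if (n_genes == 0L) {
    return(data.frame(gene = character(0), condition = character(0),
                      time_h = numeric(0), replicate = integer(0),
                      ct = numeric(0), ct_control = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (!is.matrix(ddct)) {
    ddct <- matrix(ddct, nrow = n_genes, ncol = length(times))
  }
  stopifnot(nrow(ddct) == n_genes, ncol(ddct) == length(times))
  grid <- expand.grid(replicate = 1:3, time_h = times,
                      condition = c("control", "treatment"),
                      gene = paste0("qgene", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
  gi <- as.integer(sub("qgene", "", grid$gene))
  ti <- match(grid$time_h, times)
  effect <- ifelse(grid$condition == "treatment",
                   ddct[cbind(gi, ti)], 0)
  ct_control <- stats::rnorm(nrow(grid), mean = 20, sd = ct_sd)
  dct <- 5 + effect + stats::rnorm(nrow(grid), mean = 0, sd = ct_sd)
  out <- grid[, c("gene", "condition", "time_h", "replicate")]
  out$ct <- ct_control + dct
  out$ct_control <- ct_control
  out
}

#' Simulate a qPCR Ct table
#'
#' Stand-alone wrapper around the Ct component of
#' [make_expression_data()], for differential-expression simulations.
#'
#' @inheritParams make_expression_data
#' @param ddct planted ddCt; scalar, or matrix `n_genes x length(times)`
#' @param n_genes number of target genes
#' @return long-format Ct data.frame (see [make_expression_data()])
#' @export
simulate_qpcr_ct <- function(n_genes, ddct = 0, times = c(0, 1, 5, 10),
                             ct_sd = 0.15, seed = 1L) {
  with_seed(seed, simulate_qpcr_ct_(n_genes, ddct, times, ct_sd))
}

#' Relative expression by the 2^-ddCt method
#'
#' For each gene and time point: per-replicate `dCt = Ct_target -
#' Ct_control_gene`; `ddCt = mean dCt(treatment) - mean dCt(reference)`;
#' `fold = 2^-ddCt`. The standard error is computed over per-replicate
#' folds (each treatment replicate's dCt against the reference mean) and
#' the p-value from a two-sided t test on the dCt values (Student's
#' equal-variance by default; `welch = TRUE` for unequal variances).
#' The result is invariant to additive shifts of all Ct values.
#'
#' @param ct long-format Ct data.frame with columns `gene`, `condition`,
#'   `time_h`, `replicate`, `ct`, `ct_control`
#' @param reference reference condition name
#' @param treatment treatment condition name
#' @param welch use Welch's t test instead of Student's
#' @return data.frame with `gene`, `time_h`, `ddct`, `fold`, `se`,
#'   `p_value`
#' @export
relative_expression_ddct <- function(ct, reference = "control",
                                     treatment = "treatment",
                                     welch = FALSE) {
  needed <- c("gene", "condition", "time_h", "replicate", "ct",
              "ct_control")
  stopifnot(all(needed %in% names(ct)))
  ct$dct <- ct$ct - ct$ct_control
  out <- list()
  for (g in unique(ct$gene)) {
    for (tp in sort(unique(ct$time_h[ct$gene == g]))) {
      trt <- ct$dct[ct$gene == g & ct$time_h == tp &
                    ct$condition == treatment]
      ref <- ct$dct[ct$gene == g & ct$time_h == tp &
                    ct$condition == reference]
      if (length(trt) == 0L || length(ref) == 0L) next
      if (length(trt) < 2L || length(ref) < 2L)
        stop("need at least 2 replicates per condition", call. = FALSE)
      ddct <- mean(trt) - mean(ref)
      rep_folds <- 2^-(trt - mean(ref))
      # degenerate (constant) replicates carry no significance information
      p <- tryCatch(stats::t.test(trt, ref, var.equal = !welch)$p.value,
                    error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, time_h = tp, ddct = ddct, fold = 2^-ddct,
        se = stats::sd(rep_folds) / sqrt(length(rep_folds)),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene = character(0), time_h = numeric(0),
                      ddct = numeric(0), fold = numeric(0),
                      se = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-time-point counts of significant expression changes
#'
#' @param rel output of [relative_expression_ddct()]
#' @param alpha significance level
#' @param adjust p-value adjustment method (default `"none"`, matching
#'   per-gene t testing without multiple-testing correction; any
#'   [stats::p.adjust()] method, e.g. `"BH"`, may be requested). The
#'   adjustment is applied within each time point.
#' @return data.frame with `time_h`, `n_up` (`fold > 1 & p < alpha`),
#'   `n_down` (`fold < 1 & p < alpha`), `n_tested`
#' @export
de_time_course_summary <- function(rel, alpha = 0.05, adjust = "none") {
  stopifnot(all(c("gene", "time_h", "fold", "p_value") %in% names(rel)))
  times <- sort(unique(rel$time_h))
  out <- lapply(times, function(tp) {
    sub <- rel[rel$time_h == tp, , drop = FALSE]
    p <- stats::p.adjust(sub$p_value, method = adjust)
    data.frame(time_h = tp,
               n_up = sum(sub$fold > 1 & p < alpha, na.rm = TRUE),
               n_down = sum(sub$fold < 1 & p < alpha, na.rm = TRUE),
               n_tested = nrow(sub))
  })
  do.call(rbind, out)
}
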