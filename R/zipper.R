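# Leucine-zipper heptad registers and dimerization-property statistics:
# a/d/e/g residue composition, Asn-at-a per-heptad histogram, and the
# electrostatic classification of g<->e' pairs.

ZIPPER_SLOTS <- c("a", "b", "c", "d", "e", "f", "g")
BASIC_RESIDUES <- c("R", "K")
ACIDIC_RESIDUES <- c("D", "E")

#' Assign the heptad register of a leucine zipper
#'
#' The first zipper residue (domain position +1, a leucine in canonical
#' domains) is assigned slot `d` of heptad 1, and labels continue
#' cyclically (`e f g a b c d ...`) toward the C terminus. Heptad 1's
#' `a`-`c` slots, which would fall N-terminal of +1, are absent, and a
#' trailing partial heptad keeps whatever slots its residues fill. A
#' `register_offset` rotates the anchor slot for alternative conventions.
#'
#' @param ann a [scan_domain()] annotation row (used for its zipper span)
#' @param protein the protein sequence, or `NULL` when `zipper` is given
#' @param zipper give the zipper substring directly instead of
#'   `ann`+`protein`
#' @param protein_id id stored in the register
#' @param register_offset rotation of the anchor label; 0 anchors +1 at `d`
#' @return object of class `heptad_register`: a data.frame with columns
#'   `protein_id`, `heptad`, `slot`, `residue`
#' @export
assign_register <- function(ann = NULL, protein = NULL, zipper = NULL,
                            protein_id = NULL, register_offset = 0L) {
  if (is.null(zipper)) {
    stopifnot(!is.null(ann), !is.null(protein))
    if (is.data.frame(ann)) {
      stopifnot(nrow(ann) == 1L)
      ann <- as.list(ann)
    }
    zipper <- substr(protein, ann$zipper_start, ann$zipper_end)
    if (is.null(protein_id)) protein_id <- ann$protein_id
  }
  if (is.null(protein_id)) protein_id <- "protein"
  ch <- check_aa(zipper, allow_x = TRUE, what = "zipper")
  n <- length(ch)
  if (n == 0L) stop("empty zipper", call. = FALSE)
  # slot index of residue k (k = 1 at domain position +1): d is slot 4
  raw <- (seq_len(n) - 1L) + 3L + as.integer(register_offset)
  out <- data.frame(protein_id = protein_id,
                    heptad = raw %/% 7L + 1L,
                    slot = ZIPPER_SLOTS[raw %% 7L + 1L],
                    residue = ch,
                    stringsAsFactors = FALSE)
  class(out) <- c("heptad_register", "data.frame")
  out
}

#' @keywords internal
#' @noRd
bind_registers <- function(registers) {
  if (inherits(registers, "heptad_register")) registers <- list(registers)
  stopifnot(length(registers) >= 1L)
  do.call(rbind, lapply(registers, as.data.frame))
}

#' Residue composition at the interface positions a, d, e and g
#'
#' Residues are pooled over all heptads of all registers; `X` and absent
#' slots are excluded from the denominators. These four positions line the
#' coiled-coil interface and govern dimerization stability and specificity.
#'
#' @param registers a `heptad_register` or list of them
#' @param positions slots to tabulate
#' @return named list with, per position, `freq` (named relative
#'   frequencies summing to 1) and `n` (denominator)
#' @export
composition_by_position <- function(registers,
                                    positions = c("a", "d", "e", "g")) {
  pooled <- bind_registers(registers)
  out <- lapply(positions, function(p) {
    res <- pooled$residue[pooled$slot == p & pooled$residue != "X"]
    if (length(res) == 0L) return(list(freq = numeric(0), n = 0L))
    tab <- sort(table(res), decreasing = TRUE)
    list(freq = stats::setNames(as.numeric(tab) / length(res), names(tab)),
         n = length(res))
  })
  stats::setNames(out, positions)
}

#' Per-heptad percentage of asparagine at the a position
#'
#' Asn at `a` forms a polar pocket in the hydrophobic interface enabling
#' stabilizing N-N contacts across the dimer. For each heptad index the
#' percentage is `100 * (#registers with N at that a) / (#registers with
#' any residue at that a)`.
#'
#' @param registers a `heptad_register` or list of them
#' @return data.frame with `heptad`, `n_asn`, `n_total`, `pct`
#' @export
asn_a_by_heptad <- function(registers) {
  pooled <- bind_registers(registers)
  at_a <- pooled[pooled$slot == "a" & pooled$residue != "X", , drop = FALSE]
  if (nrow(at_a) == 0L) {
    return(data.frame(heptad = integer(0), n_asn = integer(0),
                      n_total = integer(0), pct = numeric(0)))
  }
  hept <- sort(unique(at_a$heptad))
  n_total <- vapply(hept, function(h) sum(at_a$heptad == h), integer(1))
  n_asn <- vapply(hept, function(h)
    sum(at_a$heptad == h & at_a$residue == "N"), integer(1))
  data.frame(heptad = hept, n_asn = n_asn, n_total = n_total,
             pct = round(100 * n_asn / n_total, 2))
}

#' @keywords internal
#' @noRd
ge_category <- function(g, e_prime) {
  g_basic <- g %in% BASIC_RESIDUES
  g_acid <- g %in% ACIDIC_RESIDUES
  e_basic <- e_prime %in% BASIC_RESIDUES
  e_acid <- e_prime %in% ACIDIC_RESIDUES
  ifelse(g_basic & e_acid, "attractive_plus_minus",
  ifelse(g_acid & e_basic, "attractive_minus_plus",
  ifelse(g_basic & e_basic, "basic_repulsive",
  ifelse(g_acid & e_acid, "acidic_repulsive", "uncharged"))))
}

GE_CATEGORIES <- c("attractive_plus_minus", "attractive_minus_plus",
                   "basic_repulsive", "acidic_repulsive", "uncharged")

#' Classify the g<->e' electrostatic pairs of one zipper
#'
#' Pairs the `g` residue of heptad n with the `e` residue of heptad n+1 of
#' the same sequence (the homodimer self-pairing proxy) and classifies each
#' pair by charge: attractive when the two residues carry opposite charges
#' (basic = R/K, acidic = D/E; histidine counts as uncharged), repulsive
#' when like-charged, `uncharged` otherwise.
#'
#' @param register a `heptad_register`
#' @return data.frame with `heptad` (index n of the g residue),
#'   `g_residue`, `e_prime_residue`, `category`; zero rows when fewer than
#'   two heptads carry the needed slots
#' @export
#' @examples
#' r <- assign_register(zipper = "LQAKLEQLEE")   # g of heptad 1 = K, e' = E
#' classify_ge_pairs(r)
classify_ge_pairs <- function(register) {
  stopifnot(inherits(register, "heptad_register"))
  g <- register[register$slot == "g", c("heptad", "residue")]
  e <- register[register$slot == "e", c("heptad", "residue")]
  m <- merge(g, data.frame(heptad = e$heptad - 1L, e_res = e$residue),
             by = "heptad")
  m <- m[m$residue != "X" & m$e_res != "X", , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(heptad = integer(0), g_residue = character(0),
                      e_prime_residue = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  m <- m[order(m$heptad), , drop = FALSE]
  data.frame(heptad = m$heptad, g_residue = m$residue,
             e_prime_residue = m$e_res,
             category = ge_category(m$residue, m$e_res),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate g<->e' pair categories over a set of zippers
#'
#' @param registers a `heptad_register` or list of them
#' @param per_heptad when `TRUE` (default) frequencies are relative to the
#'   pairs observed at each heptad index; when `FALSE`, relative to all
#'   pairs pooled over heptads
#' @return data.frame with `heptad`, `category`, `count`, `freq`
#' @export
aggregate_ge <- function(registers, per_heptad = TRUE) {
  if (inherits(registers, "heptad_register")) registers <- list(registers)
  pairs <- do.call(rbind, lapply(registers, classify_ge_pairs))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(data.frame(heptad = integer(0), category = character(0),
                      count = integer(0), freq = numeric(0)))
  }
  tab <- as.data.frame(table(heptad = pairs$heptad,
                             category = factor(pairs$category,
                                               levels = GE_CATEGORIES)),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "count"
  tab$heptad <- as.integer(tab$heptad)
  denom <- if (per_heptad) {
    stats::ave(tab$count, tab$heptad, FUN = sum)
  } else rep(sum(tab$count), nrow(tab))
  tab$freq <- ifelse(denom > 0, tab$count / denom, 0)
  tab <- tab[order(tab$heptad, match(tab$category, GE_CATEGORIES)), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read a pre-annotated heptad-alignment table
#'
#' Ingests a TSV with one protein per row, a `protein_id` column and one
#' column per register slot named `h<heptad>_<slot>` (for example `h2_a`);
#' empty cells or `-` mark absent slots. This is the entry point for
#' externally curated zipper alignments.
#'
#' @param path TSV file path
#' @return list of `heptad_register` objects
#' @export
read_heptad_alignment <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  stopifnot("protein_id" %in% names(tab))
  slot_cols <- grep("^h[0-9]+_[a-g]$", names(tab), value = TRUE)
  if (length(slot_cols) == 0L)
    stop("no h<heptad>_<slot> columns found", call. = FALSE)
  hept <- as.integer(sub("^h([0-9]+)_.*$", "\\1", slot_cols))
  slot <- sub("^h[0-9]+_", "", slot_cols)
  lapply(seq_len(nrow(tab)), function(i) {
    res <- as.character(unlist(tab[i, slot_cols]))
    keep <- !is.na(res) & res != "" & res != "-"
    out <- data.frame(protein_id = tab$protein_id[i],
                      heptad = hept[keep], slot = slot[keep],
                      residue = res[keep], stringsAsFactors = FALSE)
    out <- out[order(out$heptad, match(out$slot, ZIPPER_SLOTS)), ,
               drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("heptad_register", "data.frame")
    out
  })
}
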