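# IMGT numbering and CDR/framework region assignment.
#
# The unique IMGT scheme numbers both variable domains 1-128 so that the
# heavy and light chains can be compared position by position. CDR limits
# (identical for both chains):
#   CDR1 27-38, CDR2 56-65, CDR3 105-117; everything else in 1-128 is
#   framework.

.IMGT_MIN <- 1L
.IMGT_MAX <- 128L
.CDR_RANGES <- list(CDR1 = c(27L, 38L), CDR2 = c(56L, 65L), CDR3 = c(105L, 117L))

#' IMGT region assignment
#'
#' Assigns an IMGT position on a heavy or light chain to one of the four
#' variable-domain regions: `CDR1` (positions 27-38), `CDR2` (56-65),
#' `CDR3` (105-117) or framework (`FW`, the remainder of 1-128). Insertion
#' ranks do not affect membership: an inserted residue belongs to the region
#' of its parent position.
#'
#' @param number integer vector of IMGT positions (1-128).
#' @param chain `"H"` or `"L"` (recycled).
#' @return character vector of region labels such as `"CDR-H1"` or `"FW-L"`.
#' @examples
#' assign_region(30, "H")   # "CDR-H1"
#' assign_region(60, "L")   # "CDR-L2"
#' assign_region(1, "H")    # "FW-H"
#' @export
assign_region <- function(number, chain) {
  number <- as.integer(number)
  chain <- match.arg(toupper(chain), c("H", "L"), several.ok = TRUE)
  if (anyNA(number) || any(number < .IMGT_MIN | number > .IMGT_MAX))
    stop("IMGT position out of range [", .IMGT_MIN, ",", .IMGT_MAX, "]",
         call. = FALSE)
  region <- rep("FW", length(number))
  for (r in names(.CDR_RANGES)) {
    rng <- .CDR_RANGES[[r]]
    region[number >= rng[1] & number <= rng[2]] <- r
  }
  region_label(chain, region)
}

#' Build canonical region label strings
#'
#' @param chain `"H"`/`"L"`.
#' @param region `"CDR1"`, `"CDR2"`, `"CDR3"` or `"FW"`.
#' @return labels like `"CDR-H1"`, `"FW-L"`.
#' @export
region_label <- function(chain, region) {
  ifelse(region == "FW", paste0("FW-", chain),
         paste0("CDR-", chain, substr(region, 4, 4)))
}

#' Parse a region label into chain and region
#' @param label e.g. `"CDR-H3"` or `"FW-L"`.
#' @return list with elements `chain` and `region`.
#' @export
parse_region_label <- function(label) {
  ok <- grepl("^CDR-[HL][123]$|^FW-[HL]$", label)
  if (!all(ok)) stop("unknown region label: ", paste(label[!ok], collapse = ", "),
                     call. = FALSE)
  chain <- ifelse(grepl("^FW", label), substr(label, 4, 4), substr(label, 5, 5))
  region <- ifelse(grepl("^FW", label), "FW",
                   paste0("CDR", substr(label, 6, 6)))
  list(chain = chain, region = region)
}

#' All six CDR labels
#' @return character vector of the six CDR region labels in H1..L3 order.
#' @export
cdr_labels <- function() {
  c("CDR-H1", "CDR-H2", "CDR-H3", "CDR-L1", "CDR-L2", "CDR-L3")
}

#' IMGT ordering key
#'
#' Total order over (position, insertion) pairs. Insertions normally sort
#' ascending after their parent position; in the CDR3 insertion region the
#' IMGT convention applies: insertions on 111 ascend after 111 while
#' insertions on 112 descend before 112, so the ordering is
#' 111 < 111.1 < 111.2 < ... < 112.2 < 112.1 < 112.
#'
#' @param number integer IMGT position.
#' @param insertion non-negative integer insertion rank (0 = none).
#' @return numeric sort key.
#' @export
imgt_order_key <- function(number, insertion = 0L) {
  number <- as.numeric(number)
  insertion <- as.numeric(insertion)
  if (any(insertion < 0)) stop("insertion rank must be >= 0", call. = FALSE)
  key <- number + insertion * 1e-3
  at112 <- number == 112 & insertion > 0
  key[at112] <- 112 - insertion[at112] * 1e-3
  key
}

#' IMGT positions occupied by a loop of a given length
#'
#' IMGT deletes positions from the middle of a CDR span when the loop is
#' shorter than the span, keeping the two ends. Used by the synthetic
#' generator; lengths above the span are refused (no insertion emission).
#'
#' @param region `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @param length loop length in residues.
#' @return sorted integer vector of IMGT positions.
#' @export
imgt_positions_for_length <- function(region, length) {
  rng <- .CDR_RANGES[[region]]
  if (is.null(rng)) stop("unknown CDR region: ", region, call. = FALSE)
  span <- rng[2] - rng[1] + 1L
  if (length < 1L) stop("loop length must be >= 1", call. = FALSE)
  if (length > span)
    stop("loop length ", length, " exceeds the ", span, "-position ", region,
         " span (insertions are not generated)", call. = FALSE)
  n_front <- ceiling(length / 2)
  n_back <- length - n_front
  pos <- c(seq(rng[1], length.out = n_front),
           if (n_back > 0) seq(rng[2], by = -1L, length.out = n_back))
  sort(as.integer(pos))
}
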