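#' The seven lesion class codes
#'
#' Class codes used throughout the package, in canonical (alphabetical) order:
#' AKIEC (actinic keratosis), BCC (basal cell carcinoma), BKL (benign
#' keratosis), DF (dermatofibroma), MEL (melanoma), NV (melanocytic nevi),
#' VASC (vascular lesion). All decision tables, confusion matrices and score
#' vectors are indexed by this order.
#'
#' @return Character vector of length 7.
#' @export
lesion_classes <- function() {
  c("AKIEC", "BCC", "BKL", "DF", "MEL", "NV", "VASC")
}

#' The malignant lesion classes
#'
#' AKIEC, BCC and MEL form the malignant group used by the malignant ROC-AUC
#' metric; BKL, DF, NV and VASC are the non-malignant group.
#'
#' @return Character vector of length 3.
#' @export
malignant_classes <- function() {
  c("AKIEC", "BCC", "MEL")
}

#' @keywords internal
n_classes <- function() 7L

# Fixed alias table: lower-cased alias -> canonical code. Unknown labels are
# hard errors upstream; silent coercion would corrupt confusion matrices.
label_alias_map <- function() {
  c(
    "akiec" = "AKIEC", "actinic keratosis" = "AKIEC",
    "bcc" = "BCC", "basal cell carcinoma" = "BCC",
    "bkl" = "BKL", "benign keratosis" = "BKL",
    "df" = "DF", "dermatofibroma" = "DF",
    "mel" = "MEL", "melanoma" = "MEL",
    "nv" = "NV", "melanocytic nevi" = "NV", "melanocytic nevus" = "NV",
    "vasc" = "VASC", "vascular lesion" = "VASC"
  )
}

#' Normalize label strings to the 7 canonical codes
#'
#' Case-insensitive; accepts the short codes and the full lesion names
#' (e.g. "Melanoma" -> "MEL"). Values that match neither are returned as NA;
#' callers decide whether that is an error.
#'
#' @param x character vector of raw labels.
#' @return character vector of canonical codes, NA where unrecognized.
#' @export
normalize_labels <- function(x) {
  map <- label_alias_map()
  key <- tolower(trimws(as.character(x)))
  out <- unname(map[key])
  out
}

#' @keywords internal
as_class_factor <- function(x) {
  factor(as.character(x), levels = lesion_classes())
}

# round-half-up at `digits` decimals, matching tabular presentation style
# (base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

clamp_unit <- function(x, tau) {
  pmin(pmax(x, tau), 1 - tau)
}
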