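## ICD-10 chapter ranges. Codes are grouped at chapter level only; the German
## modification (ICD-10-GM) agrees with the base classification at this
## granularity. A code prefix "X99" is mapped through the ordinal
## 100*(letter index) + number so that ranges spanning a letter boundary
## (e.g. C00-D48) are ordinary integer intervals.

icd10_chapter_table <- function() {
  tibble::tribble(
    ~chapter, ~from, ~to, ~label,
    "I",     "A00", "B99", "Infectious and parasitic diseases",
    "II",    "C00", "D48", "Tumors",
    "III",   "D50", "D89", "Blood and immune disorders",
    "IV",    "E00", "E90", "Endocrine, nutritional and metabolic diseases",
    "V",     "F00", "F99", "Mental and behavioural disorders",
    "VI",    "G00", "G99", "Nervous system diseases",
    "VII",   "H00", "H59", "Eye and adnexa diseases",
    "VIII",  "H60", "H95", "Ear and mastoid diseases",
    "IX",    "I00", "I99", "Circulatory system diseases",
    "X",     "J00", "J99", "Respiratory system diseases",
    "XI",    "K00", "K93", "Digestive system diseases",
    "XII",   "L00", "L99", "Skin and subcutaneous tissue diseases",
    "XIII",  "M00", "M99", "Musculoskeletal and connective tissue diseases",
    "XIV",   "N00", "N99", "Genitourinary system diseases",
    "XV",    "O00", "O99", "Pregnancy, childbirth and the puerperium",
    "XVI",   "P00", "P96", "Certain conditions originating in the perinatal period",
    "XVII",  "Q00", "Q99", "Congenital malformations",
    "XVIII", "R00", "R99", "Symptoms and abnormal findings",
    "XIX",   "S00", "T98", "Injury and poisoning",
    "XX",    "V01", "Y98", "External causes of morbidity and mortality",
    "XXI",   "Z00", "Z99", "Factors influencing health status",
    "XXII",  "U00", "U99", "Codes for special purposes"
  )
}

code_ordinal <- function(prefix) {
  letter <- substr(prefix, 1, 1)
  num <- suppressWarnings(as.integer(substr(prefix, 2, 3)))
  ifelse(letter %in% LETTERS & !is.na(num),
         (match(letter, LETTERS) - 1L) * 100L + num, NA_integer_)
}

ordinal_code <- function(ord) {
  paste0(LETTERS[ord %/% 100L + 1L], sprintf("%02d", ord %% 100L))
}

#' ICD-10 chapters as a lookup table
#'
#' @return tibble with columns `chapter` (Roman numeral), `from`/`to`
#'   (inclusive three-character code bounds) and `label`.
#' @export
icd10_chapters <- function() icd10_chapter_table()

#' Map ICD-10 codes to chapter labels
#'
#' Classifies codes such as `"I21.0"` or `"C34"` into the 22 ICD-10 chapters
#' by their three-character prefix. Codes that do not match the
#' letter-digit-digit pattern, or fall into a gap between chapter ranges
#' (e.g. `"D49"`), are labelled `"Unknown"`.
#'
#' @param code character vector of ICD-10(-GM) codes.
#' @return character vector of chapter labels, same length as `code`.
#' @export
#' @examples
#' icd10_chapter(c("I21.0", "C34.1", "Z38.0", "bad"))
icd10_chapter <- function(code) {
  tab <- icd10_chapter_table()
  lo <- code_ordinal(tab$from)
  hi <- code_ordinal(tab$to)
  prefix <- toupper(substr(as.character(code), 1, 3))
  ok <- grepl("^[A-Z][0-9]{2}$", prefix)
  ord <- rep(NA_integer_, length(prefix))
  ord[ok] <- code_ordinal(prefix[ok])
  idx <- vapply(ord, function(o) {
    if (is.na(o)) return(NA_integer_)
    w <- which(lo <= o & o <= hi)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  out <- ifelse(is.na(idx), "Unknown", tab$label[idx])
  out
}

# draw random codes whose prefixes lie inside the named chapters (generator
# support; inverse of icd10_chapter at chapter granularity)
sample_icd10_code <- function(labels) {
  tab <- icd10_chapter_table()
  i <- match(labels, tab$label)
  if (anyNA(i)) stop("unknown ICD-10 chapter label: ",
                     paste(unique(labels[is.na(i)]), collapse = ", "))
  lo <- code_ordinal(tab$from)[i]
  hi <- code_ordinal(tab$to)[i]
  ord <- lo + floor(runif(length(i)) * (hi - lo + 1))
  paste0(ordinal_code(as.integer(ord)), ".", sample(0:9, length(i), replace = TRUE))
}
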