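# Section-coverage analysis: where in an abstract do the unique PICO
# mentions of a document set fall? The coverage of a section is the
# fraction of all unique mentions (pooled over classes) that appear in that
# section.

SECTION_COLS <- c(TT = "title", BG = "background", MT = "methods",
                  RS = "results", CC = "conclusions")

# Half-up rounding (round() uses round-half-even, which is wrong for
# reporting 3-decimal coverage values).
round_half_up <- function(x, digits = 3) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Coverage table from per-section unique-mention counts
#'
#' Given `counts[class, section]` (unique mentions of each class appearing
#' in each section) and `totals[class]` (unique mentions of each class over
#' the whole document set), the coverage of section s is
#' `sum_c counts[c, s] / sum_c totals[c]`, reported half-up to 3 decimals.
#'
#' @param counts Numeric matrix with rownames P, I, C, O and colnames TT,
#'   BG, MT, RS, CC.
#' @param totals Named numeric vector (P, I, C, O).
#' @return A list of class `pico_coverage` with `counts`, `totals` and the
#'   rounded `coverage` row.
#' @export
compute_coverage_from_counts <- function(counts, totals) {
  counts <- as.matrix(counts)[entity_classes(), names(SECTION_COLS),
                              drop = FALSE]
  totals <- totals[entity_classes()]
  if (any(counts < 0) || any(totals < 0))
    stop("counts and totals must be non-negative")
  over <- which(counts > totals, arr.ind = TRUE)
  if (nrow(over))
    stop(sprintf("counts[%s, %s] exceeds the class total",
                 rownames(counts)[over[1, 1]], colnames(counts)[over[1, 2]]))
  cov <- round_half_up(colSums(counts) / sum(totals), 3)
  structure(list(counts = counts, totals = totals, coverage = cov),
            class = "pico_coverage")
}

#' @export
print.pico_coverage <- function(x, ...) {
  tab <- cbind(x$counts, Total = x$totals)
  print(tab)
  cat("Coverage ", paste(sprintf("%s=%.3f", names(x$coverage), x$coverage),
                         collapse = "  "), "\n")
  invisible(x)
}

#' Read a per-section count table
#'
#' TSV with columns `entity`, `TT`, `BG`, `MT`, `RS`, `CC`, `total`; a
#' packaged example table (unique PICO mentions of 30 manually reviewed RCT
#' abstracts) ships as `pico_section_counts.tsv`.
#'
#' @param path Path to the TSV (default: the packaged table).
#' @return A list with `counts` matrix and `totals` vector, ready for
#'   [compute_coverage_from_counts()].
#' @export
read_section_counts <- function(path = system.file("extdata",
                                                   "pico_section_counts.tsv",
                                                   package = "picopipe")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("entity", names(SECTION_COLS), "total") %in% names(df)))
  counts <- as.matrix(df[, names(SECTION_COLS)])
  rownames(counts) <- df$entity
  totals <- stats::setNames(df$total, df$entity)
  list(counts = counts, totals = totals)
}

#' Coverage table computed from an annotated corpus
#'
#' Unique mentions per class are obtained by normalized-string
#' deduplication within class over each document (the same policy as
#' [pico_record()]); a unique mention counts toward section s when its
#' string occurs (case-insensitive substring match) in any sentence of that
#' section -- so duplicate occurrences within a section do not inflate the
#' count, and repeated mentions across sections count toward each section
#' they appear in.
#'
#' @param corpus A `pico_corpus` with gold section labels on all sentences
#'   and gold entities.
#' @return A `pico_coverage`.
#' @export
coverage_from_corpus <- function(corpus) {
  labeled <- all(vapply(corpus, function(ab)
    all(!vapply(ab$sentences, function(s) is.na(s$gold_section), logical(1))),
    logical(1)))
  if (!labeled) stop("corpus lacks gold section labels on some sentences")
  counts <- matrix(0L, length(entity_classes()), length(SECTION_COLS),
                   dimnames = list(entity_classes(), names(SECTION_COLS)))
  totals <- stats::setNames(rep(0L, length(entity_classes())),
                            entity_classes())
  for (ab in corpus) {
    rec <- pico_record(ab, which = "gold")
    if (!nrow(rec$unique)) next
    section_text <- lapply(names(SECTION_COLS), function(sc) {
      sec <- SECTION_COLS[[sc]]
      sents <- if (sec == "title") list(ab$title) else
        Filter(function(s) identical(s$gold_section, sec), ab$sentences)
      normalize_mention(paste(vapply(sents, function(s) s$text, character(1)),
                              collapse = " \n "))
    })
    names(section_text) <- names(SECTION_COLS)
    for (i in seq_len(nrow(rec$unique))) {
      cls <- rec$unique$cls[i]
      totals[cls] <- totals[cls] + 1L
      for (sc in names(SECTION_COLS)) {
        if (grepl(rec$unique$text_norm[i], section_text[[sc]], fixed = TRUE))
          counts[cls, sc] <- counts[cls, sc] + 1L
      }
    }
  }
  compute_coverage_from_counts(counts, totals)
}
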