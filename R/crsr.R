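#' Parse a CRS-R score string
#'
#' The Coma Recovery Scale-Revised is reported compactly as
#' `"total(d1 d2 d3 d4 d5 d6)"` where the six digits are the subscale
#' scores in the order auditory, visual, motor, oromotor, communication,
#' arousal (e.g. `"9(132102)"`).  The parser validates each subscale
#' against its range and checks that the printed total equals the digit
#' sum.
#'
#' Stored ranges: auditory 0-4, visual 0-5, motor 0-6, oromotor 0-3,
#' communication 0-3 (the diagnostic rule cites 1-3 although the scale
#' itself tops at 2; the wider range accepts both conventions), arousal
#' 0-3; total 0-23.
#'
#' @param text Score string like `"9(132102)"`.
#' @return A `crsr_record`: list with the six subscale scores and `total`.
#' @examples
#' parse_crsr("9(132102)")
#' @export
parse_crsr <- function(text) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^([0-9]{1,2})\\(([0-9]{6})\\)$", text))[[1]]
  if (length(m) != 3L)
    stop("malformed CRS-R string '", text,
         "': expected total(d1d2d3d4d5d6)")
  total <- as.integer(m[2])
  digits <- as.integer(strsplit(m[3], "")[[1]])
  fields <- c("auditory", "visual", "motor", "oromotor", "communication",
              "arousal")
  upper <- c(auditory = 4L, visual = 5L, motor = 6L, oromotor = 3L,
             communication = 3L, arousal = 3L)
  for (i in seq_along(fields)) {
    if (digits[i] > upper[i])
      stop("subscale '", fields[i], "' = ", digits[i],
           " exceeds its maximum of ", upper[i])
  }
  if (sum(digits) != total)
    stop("total ", total, " does not equal the subscale digit sum ",
         sum(digits))
  rec <- as.list(digits)
  names(rec) <- fields
  rec$total <- total
  structure(rec, class = "crsr_record")
}

#' Format a CRS-R record back to its string form
#'
#' @param record A `crsr_record`.
#' @return The `"total(d1d2d3d4d5d6)"` string; round-trips through
#'   [parse_crsr()].
#' @export
format_crsr <- function(record) {
  stopifnot(inherits(record, "crsr_record"))
  sprintf("%d(%d%d%d%d%d%d)", record$total, record$auditory, record$visual,
          record$motor, record$oromotor, record$communication,
          record$arousal)
}

#' @export
print.crsr_record <- function(x, ...) {
  cat("CRS-R", format_crsr(x), "\n")
  invisible(x)
}

#' Rule-based CRS-R diagnosis
#'
#' Applies the clinical criteria distinguishing the minimally conscious
#' state from the vegetative state / unresponsive wakefulness syndrome:
#' MCS if \emph{any} of auditory 3-4, visual 2-5, motor 3-6, oromotor 3, or
#' communication 1-3 holds; VS if \emph{all} of auditory <= 2, visual <= 1,
#' motor <= 2, oromotor <= 2 and communication = 0 hold.  Over the valid
#' subscale ranges the two columns are mutually exclusive and exhaustive
#' (the arousal subscale does not enter the rule), which is asserted.
#'
#' @param record A `crsr_record`.
#' @return `"MCS"` or `"VS"`.
#' @export
diagnose_crsr <- function(record) {
  stopifnot(inherits(record, "crsr_record"))
  mcs <- record$auditory >= 3 || record$visual >= 2 || record$motor >= 3 ||
    record$oromotor == 3 || (record$communication >= 1 &&
                               record$communication <= 3)
  vs <- record$auditory <= 2 && record$visual <= 1 && record$motor <= 2 &&
    record$oromotor <= 2 && record$communication == 0
  if (mcs == vs)
    stop("diagnostic columns are not mutually exclusive for ",
         format_crsr(record), " - invalid record?")
  if (mcs) "MCS" else "VS"
}

#' Parse and diagnose a patient table
#'
#' Reads a patient table (as a CSV path or data frame) with at least an
#' identifier column, a recorded `diagnosis` column (`MCS` / `UWS` / `VS`)
#' and a `crsr` score-string column; parses and validates every score,
#' applies the diagnostic rule, and flags agreement between the rule and
#' the recorded diagnosis (UWS and VS are treated as synonyms).
#' Disagreements are reported, never silently corrected.
#'
#' @param patients CSV path or data frame.
#' @return A `crsr_report` data.frame: id, recorded diagnosis, the six
#'   subscale scores, total, `rule_diagnosis` and `agreement`.
#' @export
crsr_report <- function(patients) {
  if (is.character(patients)) patients <- utils::read.csv(patients)
  patients <- as.data.frame(patients)
  if (nrow(patients) == 0L) stop("empty patient table")
  need <- c("diagnosis", "crsr")
  if (!all(need %in% names(patients)))
    stop("patient table needs columns: ", paste(need, collapse = ", "))
  id <- if ("id" %in% names(patients)) patients$id else seq_len(nrow(patients))
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    rec <- tryCatch(parse_crsr(patients$crsr[i]), error = function(e)
      stop("row ", i, " (id ", id[i], "): ", conditionMessage(e),
           call. = FALSE))
    recorded <- toupper(trimws(patients$diagnosis[i]))
    recorded_norm <- if (recorded %in% c("UWS", "VS")) "VS" else recorded
    rule <- diagnose_crsr(rec)
    data.frame(id = id[i], recorded = recorded,
               auditory = rec$auditory, visual = rec$visual,
               motor = rec$motor, oromotor = rec$oromotor,
               communication = rec$communication, arousal = rec$arousal,
               total = rec$total, rule_diagnosis = rule,
               agreement = rule == recorded_norm)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("crsr_report", "data.frame")
  out
}

#' @export
print.crsr_report <- function(x, ...) {
  cat("CRS-R report:", nrow(x), "patients,",
      sum(!x$agreement), "rule/recorded disagreement(s)\n")
  print.data.frame(x)
  invisible(x)
}

#' Path to the bundled example patient table
#'
#' An 18-patient disorders-of-consciousness cohort table (recorded
#' diagnosis, age, sex, CRS-R score string, illness duration, etiology)
#' shipped for examples and validation of the CRS-R parser.
#'
#' @return File path of the CSV.
#' @export
example_patient_table <- function() {
  system.file("extdata", "doc_patients.csv", package = "fnirsdoc",
              mustWork = TRUE)
}
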