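#' Read a GWAS summary-statistic association table
#'
#' Reads a delimited text file with one row per SNP into a validated
#' association table. The canonical columns are `snp`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pval`, and optionally `eaf`, `chrom`,
#' `pos` and `n`. Files using other column names are mapped via
#' `column_map`.
#'
#' Alleles are upper-cased on read and must be single bases (A/C/G/T);
#' multi-character (indel) alleles are rejected. Rows violating the record
#' invariants (`se > 0`, `pval` in \[0,1\], effect allele different from the
#' other allele, non-empty unique SNP identifier) are reported with their
#' line numbers.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(snp = "rsid", beta = "b")`. Canonical names not listed are looked
#'   up verbatim.
#' @param sep Field separator, default tab.
#' @return A `data.frame` of class `mr_assoc` with the canonical columns.
#' @examples
#' path <- system.file("extdata", "ltl_exposure.tsv", package = "mrlite")
#' exposure <- read_association_table(path)
#' head(exposure)
#' @export
read_association_table <- function(path, column_map = NULL, sep = "\t") {
  if (!file.exists(path)) {
    stop("association table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0L) {
    stop("empty table: ", path, " has a header but no data rows",
         call. = FALSE)
  }
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  optional <- c("eaf", "chrom", "pos", "n")
  resolve <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      column_map[[canon]]
    } else {
      canon
    }
  }
  for (canon in required) {
    if (!resolve(canon) %in% names(raw)) {
      stop("required column '", resolve(canon), "' (", canon,
           ") missing from ", path, call. = FALSE)
    }
  }
  out <- data.frame(
    snp = trimws(raw[[resolve("snp")]]),
    effect_allele = toupper(trimws(raw[[resolve("effect_allele")]])),
    other_allele = toupper(trimws(raw[[resolve("other_allele")]])),
    stringsAsFactors = FALSE
  )
  # data-file line numbers: header is line 1
  line <- seq_len(nrow(raw)) + 1L
  num_errs <- character(0)
  parse_num <- function(canon) {
    txt <- raw[[resolve(canon)]]
    # tolerate unicode minus from copy-pasted tables
    val <- suppressWarnings(as.numeric(gsub("−", "-", txt)))
    bad <- is.na(val) & !is.na(txt) & nzchar(trimws(txt))
    if (any(bad)) {
      num_errs <<- c(num_errs, paste0(
        "column '", resolve(canon), "': unparseable value(s) ",
        paste0("'", txt[bad], "' (line ", line[bad], ")", collapse = ", ")))
    }
    val
  }
  out$beta <- parse_num("beta")
  out$se <- parse_num("se")
  out$pval <- parse_num("pval")
  for (canon in optional) {
    if (resolve(canon) %in% names(raw)) {
      out[[canon]] <- parse_num(canon)
    }
  }
  if (length(num_errs) > 0L) {
    stop("unparseable numeric fields in ", path, ":\n  ",
         paste(num_errs, collapse = "\n  "), call. = FALSE)
  }
  validate_assoc(out, source = path, line = line)
}

#' Validate an association table
#'
#' Checks the per-record invariants of a summary-statistic table and
#' returns it classed as `mr_assoc`. Used internally by
#' [read_association_table()] and exported so programmatically built
#' tables get the same checks.
#'
#' @param x A data.frame with canonical association columns.
#' @param source Label used in error messages.
#' @param line Optional per-row file line numbers for error reporting.
#' @return `x`, classed `c("mr_assoc", "data.frame")`.
#' @export
validate_assoc <- function(x, source = "association table", line = NULL) {
  if (is.null(line)) line <- seq_len(nrow(x))
  bad <- character(0)
  note <- function(mask, what) {
    if (any(mask, na.rm = TRUE)) {
      idx <- which(mask)
      bad <<- c(bad, paste0(what, " (line ",
                            paste(line[idx], collapse = ", "), ")"))
    }
  }
  note(!nzchar(x$snp) | is.na(x$snp), "empty snp identifier")
  note(!x$effect_allele %in% c("A", "C", "G", "T"),
       "effect_allele not a single base A/C/G/T")
  note(!x$other_allele %in% c("A", "C", "G", "T"),
       "other_allele not a single base A/C/G/T")
  note(x$effect_allele == x$other_allele, "effect_allele equals other_allele")
  note(is.na(x$beta), "missing beta")
  note(is.na(x$se) | x$se <= 0, "se missing or not > 0")
  note(is.na(x$pval) | x$pval < 0 | x$pval > 1, "pval outside [0, 1]")
  if ("eaf" %in% names(x)) {
    note(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "eaf outside (0, 1)")
  }
  dup <- duplicated(x$snp)
  note(dup, "duplicate snp identifier")
  if (length(bad) > 0L) {
    stop("invalid rows in ", source, ":\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  class(x) <- unique(c("mr_assoc", class(x)))
  x
}

#' Write an association table
#'
#' Writes the canonical tab-separated dialect read by
#' [read_association_table()]; a round trip reproduces the records
#' field for field.
#'
#' @param x An association table (data.frame with canonical columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
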