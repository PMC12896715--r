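#' Path to a packaged fixture table
#'
#' The package ships machine-readable transcriptions of the two published
#' result tables: the diagnostic screen (gene, up/down direction,
#' tumour-vs-normal p-value; 117 genes) and the prognostic screen (gene,
#' worse/better direction, p-values for DMFS, OS and RFS; 33 + 28 genes).
#' P-values printed as upper bounds (e.g. "<1e-12") are kept verbatim and
#' flagged on parsing.
#'
#' Note: the source text reports 32 worse-prognosis genes while the printed
#' worse panel has 33 rows (CKMT1A and CKMT1B appear as separate rows with
#' identical statistics).  The fixture reproduces the printed table; the
#' discrepancy is surfaced here rather than resolved.
#'
#' @param which `"table1"` (diagnostic) or `"table2"` (prognostic).
#' @return Absolute path to the TSV fixture.
#' @examples
#' emt_fixture("table1")
#' @export
emt_fixture <- function(which = c("table1", "table2")) {
  which <- match.arg(which)
  fname <- switch(which,
                  table1 = "table1_diagnostic.tsv",
                  table2 = "table2_prognostic.tsv")
  path <- system.file("extdata", fname, package = "emtsig", mustWork = TRUE)
  path
}

# Parse a p-value column that may contain "<"-prefixed upper bounds.
# Returns list(value, bound): numeric value (the bound itself when
# prefixed) and logical flag.
parse_p_column <- function(x, column, path) {
  x <- trimws(as.character(x))
  bound <- startsWith(x, "<")
  num <- suppressWarnings(as.numeric(sub("^<\\s*", "", x)))
  bad <- is.na(num) | !is.finite(num)
  if (any(bad)) {
    stop(sprintf("unparseable p-value(s) in column '%s' of '%s': %s",
                 column, path, paste(unique(x[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(num <= 0 | num > 1)) {
    stop(sprintf("p-values in column '%s' of '%s' must lie in (0, 1]",
                 column, path), call. = FALSE)
  }
  list(value = num, bound = bound)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(sprintf("'%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  d
}

check_gene_column <- function(genes, path) {
  genes <- trimws(genes)
  if (any(!nzchar(genes))) {
    stop(sprintf("empty gene symbol in '%s'", path), call. = FALSE)
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop(sprintf("duplicate gene symbol(s) in '%s': %s",
                 path, paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  genes
}

#' Read a diagnostic (tumour-vs-normal) result table
#'
#' Expects a tab-separated file with a header and columns `gene`,
#' `direction` (values `up`/`down`) and `p_value`.  A p-value written as
#' `<x` is accepted as an upper bound: it is stored as the numeric value
#' `x` with `p_bound = TRUE`.
#'
#' @param path path to the TSV file; see [emt_fixture()] for the packaged
#'   copy of the published table.
#' @return A data frame with columns `gene`, `direction` (factor with
#'   levels `up`, `down`), `p_value` and `p_bound`.
#' @examples
#' tab1 <- read_diagnostic_table(emt_fixture("table1"))
#' table(tab1$direction)
#' @export
read_diagnostic_table <- function(path) {
  d <- read_tsv_checked(path, c("gene", "direction", "p_value"))
  if (nrow(d) == 0L) {
    return(data.frame(gene = character(), direction = factor(levels = c("up", "down")),
                      p_value = numeric(), p_bound = logical(),
                      stringsAsFactors = FALSE))
  }
  gene <- check_gene_column(d$gene, path)
  dir <- trimws(d$direction)
  if (!all(dir %in% c("up", "down"))) {
    stop(sprintf("'%s': direction values must be 'up' or 'down'", path),
         call. = FALSE)
  }
  p <- parse_p_column(d$p_value, "p_value", path)
  data.frame(gene = gene, direction = factor(dir, levels = c("up", "down")),
             p_value = p$value, p_bound = p$bound, stringsAsFactors = FALSE)
}

#' Read a prognostic (three-endpoint survival) result table
#'
#' Expects a tab-separated file with columns `gene`, `direction` (values
#' `worse`/`better`) and one p-value column per endpoint: `p_dmfs`, `p_os`,
#' `p_rfs`.  Every endpoint p-value must be populated; `<x` bounds are
#' parsed as in [read_diagnostic_table()] and flagged in `p_dmfs_bound`,
#' `p_os_bound`, `p_rfs_bound`.
#'
#' @inheritParams read_diagnostic_table
#' @return A data frame with one row per gene.
#' @examples
#' tab2 <- read_prognostic_table(emt_fixture("table2"))
#' subset(tab2, gene == "ABCA12")
#' @export
read_prognostic_table <- function(path) {
  pcols <- c("p_dmfs", "p_os", "p_rfs")
  d <- read_tsv_checked(path, c("gene", "direction", pcols))
  if (nrow(d) == 0L) {
    out <- data.frame(gene = character(),
                      direction = factor(levels = c("worse", "better")),
                      stringsAsFactors = FALSE)
    for (pc in pcols) { out[[pc]] <- numeric(); out[[paste0(pc, "_bound")]] <- logical() }
    return(out)
  }
  gene <- check_gene_column(d$gene, path)
  dir <- trimws(d$direction)
  if (!all(dir %in% c("worse", "better"))) {
    stop(sprintf("'%s': direction values must be 'worse' or 'better'", path),
         call. = FALSE)
  }
  blank <- vapply(pcols, function(pc) any(!nzchar(trimws(d[[pc]])) | is.na(d[[pc]])),
                  logical(1))
  if (any(blank)) {
    stop(sprintf("'%s': missing endpoint p-value(s) in column(s): %s",
                 path, paste(pcols[blank], collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(gene = gene,
                    direction = factor(dir, levels = c("worse", "better")),
                    stringsAsFactors = FALSE)
  for (pc in pcols) {
    p <- parse_p_column(d[[pc]], pc, path)
    out[[pc]] <- p$value
    out[[paste0(pc, "_bound")]] <- p$bound
  }
  out
}

#' Write / read a signature report
#'
#' Serialises the output of [derive_signature()] as a tab-separated file
#' with a fixed column order, rows sorted by gene symbol.  The pair of
#' functions round-trips losslessly.
#'
#' @param entries data frame as returned by [derive_signature()].
#' @param path output (input) TSV path.
#' @return `write_signature_report()` returns `path` invisibly;
#'   `read_signature_report()` returns the entries data frame.
#' @examples
#' sig <- derive_signature(read_diagnostic_table(emt_fixture("table1")),
#'                         read_prognostic_table(emt_fixture("table2")))
#' f <- tempfile(fileext = ".tsv")
#' write_signature_report(sig, f)
#' nrow(read_signature_report(f))
#' @export
write_signature_report <- function(entries, path) {
  cols <- c("gene", "diagnostic_direction", "prognostic_direction",
            "class", "concordant")
  stopifnot(is.data.frame(entries), all(cols %in% names(entries)))
  if (anyDuplicated(entries$gene)) {
    stop("duplicate gene symbols in signature entries", call. = FALSE)
  }
  out <- entries[order(entries$gene), cols, drop = FALSE]
  out[] <- lapply(out, as.character)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write signature report to '%s': %s",
                 path, conditionMessage(e)), call. = FALSE)
  })
  invisible(path)
}

#' @rdname write_signature_report
#' @export
read_signature_report <- function(path) {
  d <- read_tsv_checked(path, c("gene", "diagnostic_direction",
                                "prognostic_direction", "class", "concordant"))
  d$diagnostic_direction <- factor(d$diagnostic_direction, levels = c("up", "down"))
  d$prognostic_direction <- factor(d$prognostic_direction, levels = c("worse", "better"))
  d$class <- factor(d$class, levels = c("up_worse", "down_better", "discordant"))
  d$concordant <- as.logical(d$concordant)
  d
}
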