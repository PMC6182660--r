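# Tab-separated readers and writers. Dialect: UTF-8, header row, identifiers
# in the first column, empty cells encode missing values (never sentinels).

#' Read an expression matrix from a tab-separated file
#'
#' Expects probe identifiers in the first column and sample identifiers in
#' the header row; all body cells must be numeric.
#'
#' @param path file path.
#' @return validated expression matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("expression matrix file needs id + data columns")
  probe_ids <- tab[[1L]]
  body <- tab[, -1L, drop = FALSE]
  vals <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)))
  )
  vals <- matrix(vals, nrow = nrow(body), ncol = ncol(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row ", bad[1L], " (probe ",
         probe_ids[bad[1L]], "), column ", bad[2L] + 1L,
         " (sample ", colnames(body)[bad[2L]], ")")
  }
  expression_matrix(vals, probe_ids = probe_ids,
                    sample_ids = colnames(body))
}

#' Write an expression matrix to a tab-separated file
#'
#' Round-trips losslessly with [read_expression_matrix()] at the stated
#' precision (15 significant digits).
#'
#' @param matrix expression matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(matrix, path) {
  validate_expression_matrix(matrix)
  out <- data.frame(probe_id = rownames(matrix),
                    format(matrix, digits = 15, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("probe_id", colnames(matrix))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample table from a tab-separated file
#' @param path file path.
#' @return validated sample table.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  sample_table(tab$sample_id, tab$participant_id, tab$cohort, tab$arm,
               tab$timepoint_months, tab$age_years)
}

#' Write a sample table
#' @param st sample table.
#' @param path output path.
#' @export
write_sample_table <- function(st, path) {
  validate_sample_table(st)
  utils::write.table(st, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format clinical table into clinical courses
#'
#' The table holds one row per participant visit with columns
#' `participant_id`, `visit_months`, `cpeptide_auc_nmol_l` and optionally
#' `hba1c_percent`, `insulin_u_per_kg_day`, `arm`. Empty cells mark missing
#' measurements; a column that is entirely empty for a participant is treated
#' as absent for that participant. Visits are sorted ascending; every
#' participant must have a baseline (time 0) visit.
#'
#' @param path file path.
#' @return named list of [clinical_course()] objects.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("participant_id", "visit_months") %in% names(tab))) {
    stop("clinical table needs participant_id and visit_months columns")
  }
  opt <- function(rows, col) {
    if (!col %in% names(tab)) return(NULL)
    v <- suppressWarnings(as.numeric(tab[[col]][rows]))
    if (all(is.na(v))) NULL else v
  }
  courses <- lapply(split(seq_len(nrow(tab)), tab$participant_id),
    function(rows) {
      arm <- if ("arm" %in% names(tab)) tab$arm[rows][1L] else "none"
      clinical_course(
        participant_id = tab$participant_id[rows][1L],
        visit_times_months = tab$visit_months[rows],
        cpeptide_auc_nmol_l = opt(rows, "cpeptide_auc_nmol_l"),
        hba1c_percent = opt(rows, "hba1c_percent"),
        insulin_u_per_kg_day = opt(rows, "insulin_u_per_kg_day"),
        arm = if (is.na(arm) || arm == "") "none" else arm
      )
    })
  courses[order(names(courses))]
}

#' Write clinical courses to a long-format tab-separated file
#' @param courses list of [clinical_course()] objects.
#' @param path output path.
#' @export
write_clinical_table <- function(courses, path) {
  rows <- lapply(courses, function(cc) {
    n <- length(cc$visit_times_months)
    pick <- function(x) if (is.null(x)) rep(NA_real_, n) else x
    data.frame(participant_id = cc$participant_id,
               visit_months = cc$visit_times_months,
               cpeptide_auc_nmol_l = pick(cc$cpeptide_auc_nmol_l),
               hba1c_percent = pick(cc$hba1c_percent),
               insulin_u_per_kg_day = pick(cc$insulin_u_per_kg_day),
               arm = cc$arm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a gene-set partition as a two-column table
#' @param partition [gene_set_partition()].
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  out <- data.frame(
    probe_id = c(partition$inflammatory_probes,
                 partition$regulatory_probes),
    set = rep(c("inflammatory", "regulatory"),
              c(length(partition$inflammatory_probes),
                length(partition$regulatory_probes))),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column gene-set partition table
#' @param path file path.
#' @return [gene_set_partition()].
#' @export
read_partition <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  gene_set_partition(tab$probe_id[tab$set == "inflammatory"],
                     tab$probe_id[tab$set == "regulatory"])
}

#' Read a key-value configuration file overriding threshold defaults
#'
#' One `key: value` pair per line (YAML-style scalars only); `#` starts a
#' comment. Unknown keys are rejected. Values are coerced to numeric.
#'
#' @param path file path.
#' @param base threshold list to override, default [default_thresholds()].
#' @return threshold list.
#' @export
read_threshold_config <- function(path, base = default_thresholds()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    if (!key %in% names(base)) stop("unknown threshold: ", key)
    val <- suppressWarnings(as.numeric(trimws(kv[2L])))
    if (is.na(val)) stop("non-numeric value for ", key)
    base[[key]] <- val
  }
  if (any(unlist(base) <= 0)) stop("all thresholds must be strictly positive")
  base
}
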