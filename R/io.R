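#' Write / read an association matrix as delimited text
#'
#' Square tab-separated matrix with a header row of channel labels; row
#' `i` corresponds to the `i`-th header label.
#'
#' @param M symmetric matrix with dimnames.
#' @param path file path.
#' @return `read_assoc_matrix` returns the matrix with dimnames restored.
#' @export
write_assoc_matrix <- function(M, path) {
  utils::write.table(format(M, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = colnames(M))
  invisible(path)
}

#' @rdname write_assoc_matrix
#' @export
read_assoc_matrix <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  M <- as.matrix(d)
  rownames(M) <- colnames(M)
  M
}

write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x)
    format(x, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Export an epoch set as delimited text files
#'
#' One `channels x samples` tab-separated file per trial (no header) plus a
#' metadata table (`<subject>_meta.tsv`: subject, group, block, trial,
#' hand, angle, correct, fs, file). This plain-text layout is also the
#' entry point for real recordings: lay out your own data the same way and
#' load it with [read_epochs_dir()].
#'
#' @param epochs an [epoch_set].
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata file path.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- epochs$subject_id
  files <- character(n_trials(epochs))
  for (i in seq_len(n_trials(epochs))) {
    f <- sprintf("%s_trial%04d.tsv", id, i)
    utils::write.table(
      format(epochs$data[i, , , drop = TRUE], digits = 15, trim = TRUE),
      file.path(dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    files[i] <- f
  }
  meta <- cbind(data.frame(subject = id, group = epochs$group,
                           stringsAsFactors = FALSE),
                epochs$meta,
                data.frame(fs = epochs$fs, file = files,
                           stringsAsFactors = FALSE))
  mpath <- file.path(dir, paste0(id, "_meta.tsv"))
  write_tsv(meta, mpath)
  invisible(mpath)
}

#' Load one subject's epochs from delimited text files
#'
#' Counterpart of [write_epochs()]: reads a metadata table whose `file`
#' column names one channels x samples matrix per trial (tab-separated, no
#' header, rows in montage order).
#'
#' @param meta_path path to the subject metadata table.
#' @param montage the [montage] describing the channel rows.
#' @return an [epoch_set].
#' @export
read_epochs_dir <- function(meta_path, montage = default_montage()) {
  meta <- read_tsv(meta_path)
  need <- c("subject", "group", "hand", "angle", "fs", "file")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata table lacks column(s): ", paste(miss, collapse = ", "))
  dir <- dirname(meta_path)
  first <- as.matrix(utils::read.table(file.path(dir, meta$file[1]),
                                       sep = "\t"))
  data <- array(0, c(nrow(meta), nrow(first), ncol(first)))
  data[1, , ] <- first
  for (i in seq_len(nrow(meta))[-1])
    data[i, , ] <- as.matrix(utils::read.table(file.path(dir, meta$file[i]),
                                               sep = "\t"))
  keep <- setdiff(names(meta), c("subject", "group", "fs", "file"))
  epoch_set(data, fs = meta$fs[1], montage = montage,
            meta = meta[, keep, drop = FALSE],
            subject_id = meta$subject[1], group = meta$group[1])
}

#' Read / write a flat TOML-style configuration file
#'
#' Minimal `key = value` format: numbers, `true`/`false`, quoted or bare
#' strings, and comma-separated lists in square brackets. Lines starting
#' with `#` are comments.
#'
#' @param path file path.
#' @param config named list to serialise.
#' @return `read_run_config` returns a named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (startsWith(val, "[") && endsWith(val, "]")) {
    parts <- trimws(strsplit(substr(val, 2, nchar(val) - 1), ",")[[1]])
    return(unlist(lapply(parts, parse_config_value)))
  }
  if (grepl('^".*"$', val)) return(substr(val, 2, nchar(val) - 1))
  if (val %in% c("true", "false")) return(val == "true")
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) {
    if (length(v) > 1)
      return(paste0("[", paste(vapply(v, fmt, character(1)),
                               collapse = ", "), "]"))
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15, scientific = FALSE)
  }
  writeLines(paste0(names(config), " = ",
                    vapply(config, fmt, character(1))), path)
  invisible(path)
}
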