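# Plain-text readers/writers. All coordinates are 0-based half-open
# internally and on disk (BED convention). Parsers reject rather than
# coerce malformed rows and report the offending file and line.

parse_stop <- function(path, line, msg) {
  stop(path, ":", line, ": ", msg, call. = FALSE)
}

#' Read a BED file (strict, 0-based half-open)
#'
#' Accepts 3-6 tab-separated columns (chrom, start, end, name, score,
#' strand). Rejects rows with `end <= start`, non-integer coordinates, or
#' (when `chrom_lengths` is given) unknown chromosomes, reporting the file
#' and line number.
#'
#' @param path file path.
#' @param chrom_lengths optional named vector to validate chromosomes and
#'   bounds against.
#' @return data.frame with `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand` present in the file.
#' @export
read_bed <- function(path, chrom_lengths = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3))
    parse_stop(path, idx[which(ncols < 3)[1]], "fewer than 3 columns")
  n_use <- min(ncols)
  get <- function(k) vapply(parts, `[[`, "", k)
  start_c <- get(2); end_c <- get(3)
  bad <- !grepl("^-?[0-9]+$", start_c) | !grepl("^-?[0-9]+$", end_c)
  if (any(bad)) parse_stop(path, idx[which(bad)[1]],
                           "non-integer coordinate")
  out <- data.frame(chrom = get(1), start = as.numeric(start_c),
                    end = as.numeric(end_c), stringsAsFactors = FALSE)
  bad <- out$start < 0 | out$end <= out$start
  if (any(bad))
    parse_stop(path, idx[which(bad)[1]],
               "invalid interval (need 0 <= start < end)")
  if (!is.null(chrom_lengths)) {
    unk <- !out$chrom %in% names(chrom_lengths)
    if (any(unk)) parse_stop(path, idx[which(unk)[1]],
                             paste("unknown chromosome",
                                   out$chrom[which(unk)[1]]))
    oob <- out$end > chrom_lengths[out$chrom]
    if (any(oob)) parse_stop(path, idx[which(oob)[1]],
                             "interval beyond chromosome end")
  }
  if (n_use >= 4) out$name <- get(4)
  if (n_use >= 5) out$score <- suppressWarnings(as.numeric(get(5)))
  if (n_use >= 6) out$strand <- get(6)
  out
}

#' Write a BED file
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  # BED columns are positional: stop at the first absent optional column
  want <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- which(!want %in% cols)
  cols <- if (length(upto)) want[seq_len(min(upto) - 1)] else want
  m <- df[, cols, drop = FALSE]
  m$start <- format(m$start, scientific = FALSE, trim = TRUE)
  m$end <- format(m$end, scientific = FALSE, trim = TRUE)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read contact-matrix COO triples
#'
#' Format: four whitespace-separated columns `chrom bin1 bin2 count` with
#' 0-based bin indices. Duplicate cells -- including a pair recorded both
#' as (i, j) and (j, i) -- are merged by summation with a warning.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `bin1`, `bin2` (upper triangle:
#'   `bin1 <= bin2`), `count`.
#' @export
read_coo <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^#", lines)
  idx <- which(keep)
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  ncols <- lengths(parts)
  if (any(ncols != 4))
    parse_stop(path, idx[which(ncols != 4)[1]], "expected 4 columns")
  get <- function(k) vapply(parts, `[[`, "", k)
  for (k in 2:4) {
    bad <- !grepl("^[0-9]+$", get(k))
    if (any(bad))
      parse_stop(path, idx[which(bad)[1]],
                 "bin indices and counts must be non-negative integers")
  }
  df <- data.frame(chrom = get(1), bin1 = as.numeric(get(2)),
                   bin2 = as.numeric(get(3)), count = as.numeric(get(4)),
                   stringsAsFactors = FALSE)
  # canonical upper triangle
  lo <- pmin(df$bin1, df$bin2); hi <- pmax(df$bin1, df$bin2)
  df$bin1 <- lo; df$bin2 <- hi
  key <- paste(df$chrom, df$bin1, df$bin2)
  if (anyDuplicated(key)) {
    warning("duplicate contact cells merged by summation in ", path)
    agg <- stats::aggregate(count ~ chrom + bin1 + bin2, data = df, sum)
    df <- agg[order(agg$chrom, agg$bin1, agg$bin2), ]
    rownames(df) <- NULL
  }
  df
}

#' Write a contact matrix as COO triples (upper triangle)
#'
#' @param cm a [contact_matrix()] or a named list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coo <- function(cm, path) {
  cms <- if (inherits(cm, "contact_matrix")) list(cm) else cm
  con <- file(path, "w")
  on.exit(close(con))
  for (x in cms) {
    ut <- which(upper.tri(x$mat, diag = TRUE) & x$mat != 0, arr.ind = TRUE)
    if (nrow(ut)) {
      o <- order(ut[, 1], ut[, 2])
      writeLines(sprintf("%s\t%d\t%d\t%g", x$chrom, ut[o, 1] - 1L,
                         ut[o, 2] - 1L, x$mat[ut][o]), con)
    }
  }
  invisible(path)
}

#' Read a long-format count table
#'
#' Tab-separated with header `site_id chrom start end condition replicate
#' count`. Negative counts and invalid intervals are rejected with the
#' line number.
#'
#' @param path file path.
#' @return data.frame in the same schema.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("site_id", "chrom", "start", "end", "condition", "replicate",
            "count")
  if (!all(need %in% names(df)))
    stop(path, ": missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  bad <- df$count < 0
  if (any(bad)) parse_stop(path, which(bad)[1] + 1L, "negative count")
  bad <- df$end <= df$start
  if (any(bad)) parse_stop(path, which(bad)[1] + 1L,
                           "invalid interval (need start < end)")
  df
}

#' Write a long-format count table
#'
#' @param df data.frame with the [read_counts()] schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a wide per-site two-condition count table to long format
#'
#' Helper mapping the wide tables used internally (e.g. by
#' [simulate_methylation()]) onto the on-disk long count schema.
#'
#' @param table wide data.frame with `site_id`, `chrom`, `start`, `end`
#'   plus count columns named like `hpa_wt` or `wt_1`.
#' @param count_cols named character vector mapping long
#'   `condition:replicate` keys to wide column names, e.g.
#'   `c("WT:hpa" = "hpa_wt")`.
#' @return long data.frame in the [read_counts()] schema.
#' @export
counts_long <- function(table, count_cols) {
  rows <- lapply(names(count_cols), function(k) {
    cr <- strsplit(k, ":", fixed = TRUE)[[1]]
    data.frame(site_id = table$site_id, chrom = table$chrom,
               start = table$start, end = table$end,
               condition = cr[1], replicate = cr[2],
               count = table[[count_cols[[k]]]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
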