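#' Construct a table of binding calls
#'
#' A binding call is a point call for one factor: the summit coordinate of a
#' ChIP-seq binding event (the dialect produced by summit-resolution peak
#' callers such as GPS/GEM).  Coordinates are 0-based.
#'
#' @param factor character vector of factor labels (non-empty strings).
#' @param chrom character vector of chromosome names.
#' @param summit integer vector of 0-based summit coordinates (>= 0).
#' @param motif_present optional logical vector: whether the site contains a
#'   cognate motif match of the factor (only meaningful for
#'   sequence-specific factors); `NA` when unknown.
#' @param cell_type optional character vector of cell-type labels.
#' @param strength optional non-negative numeric binding strength.
#' @return a `binding_calls` data frame with columns `factor`, `chrom`,
#'   `summit`, `motif_present`, `cell_type`, `strength`.
#' @export
binding_calls <- function(factor, chrom, summit, motif_present = NA,
                          cell_type = NA_character_, strength = NA_real_) {
  summit <- as.integer(summit)
  if (any(is.na(summit))) stop("summit coordinates must be integers")
  if (any(summit < 0)) stop("summit coordinates must be >= 0")
  if (any(!nzchar(factor))) stop("factor labels must be non-empty")
  df <- data.frame(
    factor = as.character(factor),
    chrom = as.character(chrom),
    summit = summit,
    motif_present = as.logical(motif_present),
    cell_type = as.character(cell_type),
    strength = as.numeric(strength),
    stringsAsFactors = FALSE
  )
  class(df) <- c("binding_calls", "data.frame")
  df
}

#' Read point binding calls for one factor from a TSV file
#'
#' Expects a headerless tab-separated file with columns
#' `chrom`, `summit[, motif_flag 0/1[, strength]]`.  Malformed lines are
#' reported with their line numbers.
#'
#' @param path file path.
#' @param factor factor label to attach to every record.
#' @param cell_type optional cell-type label.
#' @return a [binding_calls()] data frame.
#' @export
read_binding_calls <- function(path, factor, cell_type = NA_character_) {
  if (!file.exists(path)) stop("binding call file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no records in binding call file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2)) {
    stop("malformed line(s) (need >= 2 tab-separated columns) at line ",
         paste(which(ncols < 2), collapse = ", "), " in ", path)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  summit_raw <- vapply(parts, `[[`, "", 2L)
  summit <- suppressWarnings(as.integer(summit_raw))
  if (any(is.na(summit))) {
    stop("non-integer summit coordinate at line ",
         paste(which(is.na(summit)), collapse = ", "), " in ", path)
  }
  motif <- rep(NA, length(lines))
  if (all(ncols >= 3)) {
    raw <- vapply(parts, `[[`, "", 3L)
    motif <- raw == "1" | toupper(raw) == "TRUE"
  }
  strength <- rep(NA_real_, length(lines))
  if (all(ncols >= 4)) {
    strength <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
  }
  binding_calls(factor = factor, chrom = chrom, summit = summit,
                motif_present = motif, cell_type = cell_type,
                strength = strength)
}

#' Read all per-factor call files in a directory
#'
#' Each `<factor>.tsv` file is read with [read_binding_calls()] and the
#' results are pooled.
#'
#' @param dir directory containing `<factor>.tsv` files.
#' @param cell_type optional cell-type label for all files.
#' @return pooled [binding_calls()].
#' @export
read_calls_dir <- function(dir, cell_type = NA_character_) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0) stop("no .tsv call files in ", dir)
  out <- lapply(files, function(f) {
    read_binding_calls(f, sub("\\.tsv$", "", basename(f)), cell_type)
  })
  combine_calls(out)
}

#' Combine several binding-call tables into one
#' @param calls_list list of [binding_calls()] data frames.
#' @return pooled [binding_calls()].
#' @export
combine_calls <- function(calls_list) {
  df <- do.call(rbind, lapply(calls_list, as.data.frame))
  class(df) <- c("binding_calls", "data.frame")
  rownames(df) <- NULL
  df
}

#' Read a BED file of intervals (0-based half-open)
#'
#' Only the first three columns are used.
#'
#' @param path BED file path.
#' @return data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs >= 3 columns: ", path)
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}

#' Read a two-column protein-protein interaction pair list
#' @param path TSV with columns bait, partner (no header).
#' @return data frame with columns `bait`, `partner`.
#' @export
read_ppi <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("PPI file needs 2 columns: ", path)
  data.frame(bait = as.character(df[[1]]), partner = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Write a matrix as TSV with a leading row-name column
#' @param m matrix.
#' @param path output path.
#' @param id_col name for the row-identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  id <- if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
        else rownames(m)
  df <- data.frame(id, as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write co-binding regions as BED
#'
#' Emits `chrom`, `start`, `end` (0-based half-open), `region_id`, `n_sites`.
#'
#' @param regions a `cobinding_regions` object (see
#'   [build_cobinding_regions()]) or its `$regions` data frame.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  df <- if (is.data.frame(regions)) regions else regions$regions
  out <- df[, c("chrom", "start", "end", "region_id", "n_sites")]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-factor binding call files
#'
#' Inverse of [read_calls_dir()]: one `<factor>.tsv` per factor with columns
#' chrom, summit, motif flag (0/1, blank when unknown).
#'
#' @param calls [binding_calls()].
#' @param dir output directory (created if needed).
#' @export
write_call_files <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in unique(calls$factor)) {
    sub <- calls[calls$factor == f, ]
    flag <- ifelse(is.na(sub$motif_present), "",
                   ifelse(sub$motif_present, "1", "0"))
    df <- data.frame(sub$chrom, sub$summit, flag)
    write.table(df, file.path(dir, paste0(f, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
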