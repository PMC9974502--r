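# Exchange formats: orthogroup tables (OrthoFinder Orthogroups.tsv dialect),
# BED-like gene position tables (0-based half-open), pairwise ortholog maps,
# and the row-per-group ohnolog dataset layout. All writers emit UTF-8 with
# Unix newlines.

write_tsv <- function(df, path, col.names = TRUE) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names, eol = "\n", fileEncoding = "UTF-8",
                     na = "")
  invisible(path)
}

#' Construct an orthogroup table
#'
#' @param members A data.frame with columns `group_id`, `species`, `gene_id`
#'   (long format; one row per gene, no rows for species absent from a group).
#' @param species Character vector fixing the species set and column order;
#'   defaults to the species appearing in `members`.
#' @param group_ids Ordered group ids; defaults to order of first appearance.
#' @return An object of class `orthogroup_table` with fields `species`,
#'   `group_ids` and `members`.
#' @export
orthogroup_table <- function(members, species = NULL, group_ids = NULL) {
  stopifnot(is.data.frame(members),
            all(c("group_id", "species", "gene_id") %in% names(members)))
  members <- data.frame(group_id = as.character(members$group_id),
                        species = as.character(members$species),
                        gene_id = as.character(members$gene_id),
                        stringsAsFactors = FALSE)
  if (is.null(species)) species <- unique(members$species)
  if (is.null(group_ids)) group_ids <- unique(members$group_id)
  if (anyDuplicated(group_ids))
    stop("duplicate group ids", call. = FALSE)
  extra <- setdiff(members$species, species)
  if (length(extra))
    stop("members contain species not in the species set: ",
         paste(extra, collapse = ", "), call. = FALSE)
  dup <- duplicated(members[c("species", "gene_id")])
  if (any(dup))
    stop("gene ids duplicated within a species: ",
         paste(utils::head(members$gene_id[dup], 3), collapse = ", "),
         call. = FALSE)
  structure(list(species = as.character(species),
                 group_ids = as.character(group_ids),
                 members = members),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("Orthogroup table:", length(x$group_ids), "groups,",
      nrow(x$members), "genes,", length(x$species), "species (",
      paste(x$species, collapse = ", "), ")\n")
  invisible(x)
}

split_cell <- function(cell) {
  cell <- trimws(cell)
  if (cell == "") return(character())
  trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
}

#' Read an orthogroup table (Orthogroups.tsv dialect)
#'
#' Parses the tab-separated orthogroup layout emitted by orthology-clustering
#' software: a header row naming the group-id column and one column per
#' species, then one row per orthogroup with comma-separated gene lists in the
#' species cells (both `", "` and `","` separators are accepted; empty cell
#' means no member).
#'
#' @param path Path to the TSV file.
#' @return An [orthogroup_table()].
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty orthogroup file (no header): ", path,
                           call. = FALSE)
  # keep trailing empty fields: strsplit drops them, so pad with a sentinel
  fields <- function(line) {
    f <- strsplit(paste0(line, "\x01"), "\t", fixed = TRUE)[[1L]]
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  }
  header <- fields(lines[1L])
  if (length(header) < 2L)
    stop("orthogroup header must name at least one species", call. = FALSE)
  species <- header[-1L]
  rows <- lines[-1L]
  rows <- rows[nzchar(rows)]
  out <- vector("list", length(rows))
  ids <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- fields(rows[i])
    if (length(f) != length(header))
      stop(sprintf("ragged row at line %d: expected %d fields, got %d",
                   i + 1L, length(header), length(f)), call. = FALSE)
    ids[i] <- f[1L]
    genes <- lapply(f[-1L], split_cell)
    n <- lengths(genes)
    if (sum(n))
      out[[i]] <- data.frame(group_id = f[1L],
                             species = rep(species, n),
                             gene_id = unlist(genes, use.names = FALSE),
                             stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ids))
    stop("duplicate group id: ", ids[duplicated(ids)][1L], call. = FALSE)
  members <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(members))
    members <- data.frame(group_id = character(), species = character(),
                          gene_id = character(), stringsAsFactors = FALSE)
  orthogroup_table(members, species = species, group_ids = ids)
}

#' Write an orthogroup table in the canonical dialect
#'
#' Cells are `", "`-joined gene lists; empty cells denote absence. Reading the
#' written file back reproduces the table byte-for-byte.
#'
#' @param x An [orthogroup_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(x, path) {
  stopifnot(inherits(x, "orthogroup_table"))
  key <- paste(x$members$group_id, x$members$species, sep = "\r")
  cells <- vapply(split(x$members$gene_id, key), paste, "", collapse = ", ")
  lines <- vapply(x$group_ids, function(g) {
    row <- vapply(x$species, function(s) {
      v <- cells[paste(g, s, sep = "\r")]
      if (is.na(v)) "" else v
    }, "")
    paste(c(g, row), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(c("Orthogroup", x$species), collapse = "\t"), lines),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Construct a gene position table
#'
#' Coordinates are 0-based half-open (BED convention).
#'
#' @param records data.frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @param species Species label for the table.
#' @return An object of class `gene_position_table`.
#' @export
gene_position_table <- function(records, species) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "start", "end", "gene_id") %in% names(records)))
  records <- data.frame(chrom = as.character(records$chrom),
                        start = records$start, end = records$end,
                        gene_id = as.character(records$gene_id),
                        stringsAsFactors = FALSE)
  if (nrow(records)) {
    if (!is.numeric(records$start) || !is.numeric(records$end) ||
        any(records$start != round(records$start)) ||
        any(records$end != round(records$end)))
      stop("coordinates must be integers", call. = FALSE)
    if (any(records$start < 0) || any(records$start >= records$end))
      stop("invalid interval: require 0 <= start < end", call. = FALSE)
    if (anyDuplicated(records$gene_id))
      stop("duplicate gene ids in position table: ",
           records$gene_id[duplicated(records$gene_id)][1L], call. = FALSE)
  }
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  structure(list(species = as.character(species), records = records),
            class = "gene_position_table")
}

#' @export
print.gene_position_table <- function(x, ...) {
  cat("Gene positions for", x$species, ":", nrow(x$records), "genes on",
      length(unique(x$records$chrom)), "chromosomes\n")
  invisible(x)
}

#' Read a BED-like gene position table
#'
#' Expects a headerless TSV with at least four columns: chromosome, start,
#' end, gene id (0-based half-open coordinates). Extra columns are ignored.
#'
#' @param path Path to the file.
#' @param species Species label to attach.
#' @return A [gene_position_table()].
#' @export
read_gene_positions <- function(path, species) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(gene_position_table(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 gene_id = character(), stringsAsFactors = FALSE), species))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L))
    stop("position table needs >= 4 columns at line ",
         which(lengths(parts) < 4L)[1L], call. = FALSE)
  starts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends))
    stop("non-integer coordinate at line ",
         which(is.na(starts) | is.na(ends))[1L], call. = FALSE)
  gene_position_table(
    data.frame(chrom = vapply(parts, `[`, "", 1L),
               start = starts, end = ends,
               gene_id = vapply(parts, `[`, "", 4L),
               stringsAsFactors = FALSE), species)
}

#' Write a gene position table as BED-like TSV
#'
#' @param x A [gene_position_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(x, path) {
  stopifnot(inherits(x, "gene_position_table"))
  write_tsv(x$records, path, col.names = FALSE)
}

#' Construct a pairwise ortholog map
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (possibly
#'   many-to-many, but no duplicated pair).
#' @param species_a,species_b Species labels for the two columns.
#' @return An object of class `ortholog_pair_map`.
#' @export
ortholog_pair_map <- function(pairs, species_a, species_b) {
  stopifnot(is.data.frame(pairs),
            all(c("gene_a", "gene_b") %in% names(pairs)))
  pairs <- data.frame(gene_a = as.character(pairs$gene_a),
                      gene_b = as.character(pairs$gene_b),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(pairs))
    stop("duplicate ortholog pairs", call. = FALSE)
  structure(list(species_a = species_a, species_b = species_b, pairs = pairs),
            class = "ortholog_pair_map")
}

#' Read a two-column pairwise ortholog map (TSV, no header)
#'
#' @param path Path to the file.
#' @param species_a,species_b Species labels for columns 1 and 2.
#' @return An [ortholog_pair_map()].
#' @export
read_ortholog_pairs <- function(path, species_a, species_b) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(ortholog_pair_map(
      data.frame(gene_a = character(), gene_b = character(),
                 stringsAsFactors = FALSE), species_a, species_b))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("pair table needs 2 columns at line ",
         which(lengths(parts) < 2L)[1L], call. = FALSE)
  ortholog_pair_map(
    data.frame(gene_a = vapply(parts, `[`, "", 1L),
               gene_b = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE), species_a, species_b)
}

#' Write a pairwise ortholog map
#'
#' @param x An [ortholog_pair_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_pairs <- function(x, path) {
  stopifnot(inherits(x, "ortholog_pair_map"))
  write_tsv(x$pairs, path, col.names = FALSE)
}

#' Read a row-per-group ohnolog dataset
#'
#' Reads the supplementary-style ohnolog layout: one row per ohnolog group
#' with a group id, the anchoring outgroup chromosome, one comma-separated
#' member-list column per (species, slot) combination named
#' `<species>_<slot>`, and optional per-species novelty flag columns named
#' `novel_<species>`. Both TSV exports and XLSX spreadsheets (via the readxl
#' package) are supported. Column names can be remapped through `columns` so
#' that externally produced exports with different headers can be ingested.
#'
#' @param path Path to a `.tsv`/`.txt` or `.xlsx` file.
#' @param columns Named list remapping expected roles to actual column names:
#'   `group_id`, `anchor`; member and novelty columns are matched by the
#'   `member_pattern` / `novelty_pattern` regular expressions (first capture =
#'   species, second capture = slot for members).
#' @param member_pattern,novelty_pattern Regular expressions used to recognise
#'   member-list and novelty columns.
#' @param sheet Sheet index or name for XLSX input.
#' @return A list with `groups` (data.frame `group_id`, `anchor_chrom`,
#'   `species`, `slot`, `gene_id`) and `novelty` (data.frame `group_id`,
#'   `species`, `novel`), of class `ohnolog_dataset`.
#' @export
read_ohnolog_dataset <- function(path,
                                 columns = list(group_id = "group_id",
                                                anchor = "anchor_chrom"),
                                 member_pattern = "^(.+)_([A-Z])$",
                                 novelty_pattern = "^novel_(.+)$",
                                 sheet = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package", call. = FALSE)
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                           col_types = "text"))
  } else {
    df <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE)
  }
  need <- unlist(columns[c("group_id", "anchor")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("ohnolog dataset is missing expected column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  other <- setdiff(names(df), need)
  member_cols <- other[grepl(member_pattern, other)]
  novelty_cols <- other[grepl(novelty_pattern, other)]
  member_cols <- setdiff(member_cols, novelty_cols)
  groups <- list()
  for (col in member_cols) {
    sp <- sub(member_pattern, "\\1", col)
    slot <- sub(member_pattern, "\\2", col)
    genes <- lapply(ifelse(is.na(df[[col]]), "", df[[col]]), split_cell)
    n <- lengths(genes)
    if (sum(n))
      groups[[col]] <- data.frame(
        group_id = rep(df[[columns$group_id]], n),
        anchor_chrom = rep(df[[columns$anchor]], n),
        species = sp, slot = slot,
        gene_id = unlist(genes, use.names = FALSE),
        stringsAsFactors = FALSE)
  }
  groups <- if (length(groups)) do.call(rbind, groups) else
    data.frame(group_id = character(), anchor_chrom = character(),
               species = character(), slot = character(),
               gene_id = character(), stringsAsFactors = FALSE)
  groups <- groups[order(match(groups$group_id, df[[columns$group_id]]),
                         groups$species, groups$slot), , drop = FALSE]
  rownames(groups) <- NULL
  novelty <- do.call(rbind, lapply(novelty_cols, function(col) {
    data.frame(group_id = df[[columns$group_id]],
               species = sub(novelty_pattern, "\\1", col),
               novel = tolower(trimws(df[[col]])) %in%
                 c("true", "yes", "1", "new"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(novelty))
    novelty <- data.frame(group_id = character(), species = character(),
                          novel = logical(), stringsAsFactors = FALSE)
  structure(list(groups = groups, novelty = novelty,
                 group_ids = df[[columns$group_id]]),
            class = "ohnolog_dataset")
}
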