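# Portable tab-delimited microhaplotype database: markers, populations,
# frequencies, plus ancillary cross-reference tables. All tables are plain
# text (UTF-8, LF, tab-delimited, header row) so a database directory can be
# inspected, versioned and edited with ordinary tools.

MARKER_COLS <- c("Name", "Source", "Chrom", "Offsets", "Ae", "In", "Fst", "RSIDs")
POP_COLS <- c("ID", "Name", "Source")
FREQ_COLS <- c("Marker", "Population", "Allele", "Frequency", "Count")
SEQ_COLS <- c("Marker", "Start", "Sequence")
IDMAP_COLS <- c("ID", "Name")
VARMAP_COLS <- c("RSID", "Marker")

empty_df <- function(cols, numeric_cols = character(0), integer_cols = character(0)) {
  out <- lapply(cols, function(cl) {
    if (cl %in% numeric_cols) numeric(0)
    else if (cl %in% integer_cols) integer(0)
    else character(0)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Construct a microhaplotype database object
#'
#' Bundles the three core tables (markers, populations, frequencies) and the
#' optional ancillary tables (identifier cross-reference, rsID-to-marker map,
#' marker flanking sequences) into a validated database object.
#'
#' @param markers data frame with columns `Name`, `Source`, `Chrom`,
#'   `Offsets` (comma-joined 1-based variant positions), `Ae`, `In`, `Fst`
#'   (numeric summary statistics, `NA` when not yet computed) and `RSIDs`
#'   (comma-joined variant identifiers, parallel to `Offsets`).
#' @param populations data frame with columns `ID`, `Name`, `Source`.
#' @param frequencies data frame with columns `Marker`, `Population`,
#'   `Allele` (comma-joined haplotype allele tokens), `Frequency`, `Count`.
#' @param idmap optional data frame mapping third-party identifiers (`ID`)
#'   to canonical marker names (`Name`).
#' @param variantmap optional data frame mapping variant `RSID`s to `Marker`
#'   names.
#' @param sequences optional data frame with `Marker`, `Start` (1-based
#'   coordinate of the first stored base) and `Sequence` (flanking sequence
#'   spanning the marker).
#' @param validate validate invariants (referential integrity, frequency
#'   sums, offset ordering) before returning.
#' @param renormalize if `TRUE`, per-(marker, population) frequency groups
#'   are rescaled to sum to exactly 1. By default the values are preserved
#'   as given and only checked against the rounding tolerance.
#' @param freq_tol tolerance on `|sum(frequencies) - 1|` per (marker,
#'   population) group; published tables are typically rounded to 3
#'   decimals, hence the 0.005 default.
#' @return An object of class `mhdb`: a list with elements `markers`,
#'   `populations`, `frequencies`, `idmap`, `variantmap`, `sequences`.
#' @seealso [load_database()], [write_database()], [merge_sources()]
#' @export
mhdb <- function(markers, populations, frequencies,
                 idmap = NULL, variantmap = NULL, sequences = NULL,
                 validate = TRUE, renormalize = FALSE, freq_tol = 0.005) {
  markers <- as_marker_table(markers)
  populations <- as_pop_table(populations)
  frequencies <- as_freq_table(frequencies)
  db <- structure(
    list(
      markers = markers,
      populations = populations,
      frequencies = frequencies,
      idmap = if (is.null(idmap)) empty_df(IDMAP_COLS) else as.data.frame(idmap, stringsAsFactors = FALSE),
      variantmap = if (is.null(variantmap)) empty_df(VARMAP_COLS) else as.data.frame(variantmap, stringsAsFactors = FALSE),
      sequences = if (is.null(sequences)) empty_df(SEQ_COLS, integer_cols = "Start") else as.data.frame(sequences, stringsAsFactors = FALSE)
    ),
    class = "mhdb"
  )
  if (renormalize) db <- renormalize_frequencies(db)
  if (validate) validate_mhdb(db, freq_tol = freq_tol)
  db
}

as_marker_table <- function(markers) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  for (cl in c("Ae", "In", "Fst")) {
    if (!cl %in% names(markers)) markers[[cl]] <- NA_real_
    markers[[cl]] <- as.numeric(markers[[cl]])
  }
  missing <- setdiff(MARKER_COLS, names(markers))
  if (length(missing)) stop("marker table missing column(s): ", paste(missing, collapse = ", "))
  markers$Chrom <- norm_chrom(markers$Chrom)
  markers[MARKER_COLS]
}

as_pop_table <- function(populations) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  missing <- setdiff(POP_COLS, names(populations))
  if (length(missing)) stop("population table missing column(s): ", paste(missing, collapse = ", "))
  populations[POP_COLS]
}

as_freq_table <- function(frequencies) {
  frequencies <- as.data.frame(frequencies, stringsAsFactors = FALSE)
  if (!"Count" %in% names(frequencies)) frequencies$Count <- NA_integer_
  missing <- setdiff(FREQ_COLS, names(frequencies))
  if (length(missing)) stop("frequency table missing column(s): ", paste(missing, collapse = ", "))
  frequencies$Frequency <- as.numeric(frequencies$Frequency)
  frequencies$Count <- suppressWarnings(as.integer(frequencies$Count))
  frequencies[FREQ_COLS]
}

#' Validate a microhaplotype database
#'
#' Checks all type invariants: every marker has >= 2 component variants with
#' strictly increasing positions and a parallel rsID list; population IDs are
#' unique; every frequency record references an existing marker and
#' population, carries one allele token per component variant, lies in
#' \[0, 1\], and per-(marker, population) groups sum to 1 within `freq_tol`;
#' every `variantmap` rsID occurs in some marker definition. Markers whose
#' names do not follow the standard `mh<chrom><lab>-<id>` nomenclature are
#' flagged with a warning but accepted (legacy designators exist).
#'
#' @param db an `mhdb` object.
#' @param freq_tol tolerance on per-group frequency sums.
#' @return `db`, invisibly. Errors identify the offending row.
#' @export
validate_mhdb <- function(db, freq_tol = 0.005) {
  mk <- db$markers
  if (anyDuplicated(mk$Name)) {
    stop("duplicate marker name(s): ",
         paste(unique(mk$Name[duplicated(mk$Name)]), collapse = ", "))
  }
  pos <- int_csv(mk$Offsets)
  rsid <- split_csv(mk$RSIDs)
  for (i in seq_len(nrow(mk))) {
    p <- pos[[i]]
    if (length(p) < 2) {
      stop("marker '", mk$Name[i], "': a microhaplotype needs >= 2 component variants")
    }
    if (anyNA(p) || any(diff(p) <= 0)) {
      stop("marker '", mk$Name[i], "': positions must be strictly increasing integers")
    }
    if (length(rsid[[i]]) != length(p)) {
      stop("marker '", mk$Name[i], "': RSIDs and Offsets must have the same length")
    }
  }
  nonstd <- mk$Name[!is_standard_marker_name(mk$Name)]
  if (length(nonstd)) {
    warning("marker name(s) not in standard mh<chrom><lab>-<id> nomenclature: ",
            paste(nonstd, collapse = ", "))
  }

  pp <- db$populations
  if (anyDuplicated(pp$ID)) {
    stop("duplicate population ID(s): ",
         paste(unique(pp$ID[duplicated(pp$ID)]), collapse = ", "))
  }

  fq <- db$frequencies
  if (nrow(fq)) {
    bad <- which(!fq$Marker %in% mk$Name)
    if (length(bad)) {
      stop("frequency row ", bad[1], " references unknown marker '", fq$Marker[bad[1]], "'")
    }
    bad <- which(!fq$Population %in% pp$ID)
    if (length(bad)) {
      stop("frequency row ", bad[1], " references unknown population '", fq$Population[bad[1]], "'")
    }
    nvar <- lengths(pos)[match(fq$Marker, mk$Name)]
    ntok <- lengths(split_csv(fq$Allele))
    bad <- which(ntok != nvar)
    if (length(bad)) {
      stop("frequency row ", bad[1], " ('", fq$Marker[bad[1]], "', '", fq$Allele[bad[1]],
           "'): haplotype has ", ntok[bad[1]], " allele token(s) but the marker has ",
           nvar[bad[1]], " component variants")
    }
    bad <- which(is.na(fq$Frequency) | fq$Frequency < 0 | fq$Frequency > 1)
    if (length(bad)) {
      stop("frequency row ", bad[1], ": frequency ", fq$Frequency[bad[1]], " outside [0, 1]")
    }
    grp <- paste(fq$Marker, fq$Population, sep = "\r")
    sums <- tapply(fq$Frequency, grp, sum)
    off <- which(abs(sums - 1) > freq_tol)
    if (length(off)) {
      key <- strsplit(names(sums)[off[1]], "\r", fixed = TRUE)[[1]]
      stop("frequencies for marker '", key[1], "', population '", key[2],
           "' sum to ", format(sums[off[1]], digits = 6),
           " (tolerance |sum - 1| <= ", freq_tol,
           "); use renormalize = TRUE to rescale explicitly")
    }
    if (any(!is.na(fq$Count) & fq$Count < 0)) stop("negative haplotype count in frequency table")
  }

  vm <- db$variantmap
  if (nrow(vm)) {
    known <- unique(unlist(rsid))
    bad <- which(!vm$RSID %in% known)
    if (length(bad)) {
      stop("variantmap row ", bad[1], ": rsID '", vm$RSID[bad[1]],
           "' does not occur in any marker definition")
    }
  }
  if (nrow(db$sequences)) {
    bad <- which(!db$sequences$Marker %in% mk$Name)
    if (length(bad)) {
      stop("sequence row ", bad[1], " references unknown marker '",
           db$sequences$Marker[bad[1]], "'")
    }
  }
  invisible(db)
}

renormalize_frequencies <- function(db) {
  fq <- db$frequencies
  if (nrow(fq)) {
    grp <- paste(fq$Marker, fq$Population, sep = "\r")
    sums <- tapply(fq$Frequency, grp, sum)
    fq$Frequency <- fq$Frequency / as.numeric(sums[grp])
    db$frequencies <- fq
  }
  db
}

#' Retrieve one marker definition
#'
#' @param db an `mhdb` object, or a marker table in the `mhdb` dialect.
#' @param name marker name.
#' @return A list of class `mh_marker` with elements `name`, `chrom`,
#'   `positions` (integer, 1-based), `rsids`, `source`.
#' @export
marker_def <- function(db, name) {
  mk <- if (inherits(db, "mhdb")) db$markers else as_marker_table(db)
  i <- match(name, mk$Name)
  if (is.na(i)) stop("unknown marker: ", name)
  as_marker(mk[i, , drop = FALSE])
}

#' Coerce to a marker definition
#'
#' Accepts an `mh_marker` list, a one-row marker table, or a plain list with
#' `name`, `chrom`, `positions`, `rsids` (and optionally `source`).
#'
#' @param x object to coerce.
#' @return An `mh_marker` list.
#' @export
as_marker <- function(x) {
  if (inherits(x, "mh_marker")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    out <- list(
      name = x$Name,
      chrom = norm_chrom(x$Chrom),
      positions = int_csv(x$Offsets)[[1]],
      rsids = split_csv(x$RSIDs)[[1]],
      source = if ("Source" %in% names(x)) x$Source else NA_character_
    )
  } else {
    stopifnot(is.list(x), !is.null(x$positions))
    out <- list(
      name = x$name %||% NA_character_,
      chrom = norm_chrom(x$chrom),
      positions = as.integer(x$positions),
      rsids = as.character(x$rsids),
      source = x$source %||% NA_character_
    )
  }
  stopifnot(length(out$positions) == length(out$rsids))
  structure(out, class = "mh_marker")
}

# Deterministic total ordering: chromosome (1..22, X, Y), start, name.
sort_markers <- function(mk) {
  start <- vapply(int_csv(mk$Offsets), min, integer(1))
  mk[order(chrom_rank(mk$Chrom), sub("^chr", "", mk$Chrom), start, mk$Name,
           method = "radix"), , drop = FALSE]
}

sort_frequencies <- function(fq) {
  fq[order(fq$Marker, fq$Population, fq$Allele, method = "radix"), , drop = FALSE]
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", na.strings = character(0),
                    check.names = FALSE, comment.char = "",
                    fileEncoding = "UTF-8")
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cells <- vapply(df, as.character, character(nrow(df)))
    if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
    cells[is.na(cells)] <- ""
    writeLines(apply(cells, 1, paste, collapse = "\t"), con, sep = "\n")
  }
}

fmt_stat <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.4f", x))
fmt_freq <- function(x) sprintf("%.10g", x)

#' Load a microhaplotype database from a directory
#'
#' Reads the core tables `marker.tsv`, `population.tsv`, `frequency.tsv`
#' (all required) and the ancillary tables `idmap.tsv`, `variantmap.tsv`,
#' `sequence.tsv` (optional) from `dir`, then validates all invariants.
#'
#' @param dir directory containing the database files.
#' @param renormalize rescale each (marker, population) frequency group to
#'   sum to exactly 1 (never done silently).
#' @param freq_tol tolerance on per-group frequency sums.
#' @return A validated `mhdb` object.
#' @examples
#' dir <- tempfile()
#' sim <- simulate_markers(3, seed = 7)
#' db <- mhdb(sim$markers, data.frame(ID = "P1", Name = "Pop 1", Source = "sim"),
#'            empty_frequency_table())
#' write_database(db, dir)
#' db2 <- load_database(dir)
#' nrow(db2$markers)
#' @export
load_database <- function(dir, renormalize = FALSE, freq_tol = 0.005) {
  required <- c(markers = "marker.tsv", populations = "population.tsv",
                frequencies = "frequency.tsv")
  paths <- file.path(dir, required)
  miss <- !file.exists(paths)
  if (any(miss)) {
    stop("required database table(s) missing from ", dir, ": ",
         paste(required[miss], collapse = ", "))
  }
  markers <- read_tsv(paths[1])
  populations <- read_tsv(paths[2])
  frequencies <- read_tsv(paths[3])
  for (cl in c("Ae", "In", "Fst")) {
    if (!is.null(markers[[cl]])) {
      markers[[cl]] <- suppressWarnings(as.numeric(ifelse(markers[[cl]] == "", NA, markers[[cl]])))
    }
  }
  frequencies$Frequency <- as.numeric(frequencies$Frequency)
  frequencies$Count <- suppressWarnings(as.integer(ifelse(frequencies$Count == "", NA, frequencies$Count)))

  opt <- function(fn, cols, intcols = character(0)) {
    p <- file.path(dir, fn)
    if (!file.exists(p)) return(NULL)
    df <- read_tsv(p)
    for (cl in intcols) df[[cl]] <- as.integer(df[[cl]])
    df[cols]
  }
  mhdb(markers, populations, frequencies,
       idmap = opt("idmap.tsv", IDMAP_COLS),
       variantmap = opt("variantmap.tsv", VARMAP_COLS),
       sequences = opt("sequence.tsv", SEQ_COLS, "Start"),
       renormalize = renormalize, freq_tol = freq_tol)
}

#' Write a microhaplotype database to a directory
#'
#' Emits the tab-delimited tables (UTF-8, LF line endings, header row).
#' `load_database(write_database(db, dir))` reproduces `db` field for field:
#' text fields byte-identical, summary statistics at 4 decimal places,
#' frequencies at full double precision.
#'
#' @param db a validated `mhdb` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  stopifnot(inherits(db, "mhdb"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- db$markers
  for (cl in c("Ae", "In", "Fst")) mk[[cl]] <- fmt_stat(mk[[cl]])
  write_tsv(mk, file.path(dir, "marker.tsv"))
  write_tsv(db$populations, file.path(dir, "population.tsv"))
  fq <- db$frequencies
  fq$Frequency <- fmt_freq(fq$Frequency)
  write_tsv(fq, file.path(dir, "frequency.tsv"))
  if (nrow(db$idmap)) write_tsv(db$idmap, file.path(dir, "idmap.tsv"))
  if (nrow(db$variantmap)) write_tsv(db$variantmap, file.path(dir, "variantmap.tsv"))
  if (nrow(db$sequences)) write_tsv(db$sequences, file.path(dir, "sequence.tsv"))
  invisible(dir)
}

#' Empty core tables
#'
#' Convenience constructors for databases built incrementally.
#' @return A zero-row data frame in the corresponding table dialect.
#' @export
empty_frequency_table <- function() {
  empty_df(FREQ_COLS, numeric_cols = "Frequency", integer_cols = "Count")
}

#' @rdname empty_frequency_table
#' @export
empty_marker_table <- function() {
  empty_df(MARKER_COLS, numeric_cols = c("Ae", "In", "Fst"))
}

#' Merge independently curated database sources
#'
#' Takes the union of records across sources. Identical marker definitions
#' (same name, chromosome, positions, rsIDs) are collapsed to one row, with
#' their source labels joined by `";"`. Markers that share a name but differ
#' in definition are *both* retained: later conflicting definitions are
#' renamed `<name>.2`, `<name>.3`, ... and the collision is reported (see
#' the `collisions` attribute of the result). Duplicate population and
#' frequency rows are collapsed. Markers are sorted by (chromosome, start,
#' name) and frequencies by (marker, population, haplotype), so the merge is
#' deterministic and idempotent.
#'
#' @param sources list of `mhdb` objects, each independently valid.
#' @param quiet suppress the collision message.
#' @return A merged `mhdb`; `attr(, "collisions")` holds the names of
#'   markers with conflicting definitions (empty character vector if none).
#' @export
merge_sources <- function(sources, quiet = FALSE) {
  stopifnot(length(sources) >= 1, all(vapply(sources, inherits, logical(1), "mhdb")))
  mk <- do.call(rbind, lapply(sources, `[[`, "markers"))
  defkey <- paste(mk$Name, mk$Chrom, mk$Offsets, mk$RSIDs, sep = "\r")
  # collapse identical definitions, merging source labels
  first <- !duplicated(defkey)
  src <- tapply(mk$Source, defkey, function(s) paste(unique(unlist(strsplit(s, ";", fixed = TRUE))), collapse = ";"))
  mk <- mk[first, , drop = FALSE]
  mk$Source <- as.character(src[defkey[first]])
  # same name, different definition: retain both under distinct names
  collisions <- unique(mk$Name[duplicated(mk$Name)])
  if (length(collisions)) {
    for (nm in collisions) {
      idx <- which(mk$Name == nm)
      mk$Name[idx[-1]] <- paste0(nm, ".", seq_along(idx[-1]) + 1L)
    }
    if (!quiet) {
      message("marker name collision(s) with differing definitions, all retained: ",
              paste(collisions, collapse = ", "))
    }
  }
  mk <- sort_markers(mk)

  pp <- do.call(rbind, lapply(sources, `[[`, "populations"))
  pp <- pp[!duplicated(pp), , drop = FALSE]
  dup_id <- unique(pp$ID[duplicated(pp$ID)])
  if (length(dup_id)) {
    if (!quiet) {
      message("population ID collision(s), first definition kept: ",
              paste(dup_id, collapse = ", "))
    }
    pp <- pp[!duplicated(pp$ID), , drop = FALSE]
  }
  pp <- pp[order(pp$ID, method = "radix"), , drop = FALSE]

  fq <- do.call(rbind, lapply(sources, `[[`, "frequencies"))
  fq <- sort_frequencies(fq[!duplicated(fq), , drop = FALSE])

  union_tab <- function(name) {
    tab <- do.call(rbind, lapply(sources, `[[`, name))
    if (is.null(tab) || !nrow(tab)) return(NULL)
    tab[!duplicated(tab), , drop = FALSE]
  }
  out <- mhdb(mk, pp, fq,
              idmap = union_tab("idmap"),
              variantmap = union_tab("variantmap"),
              sequences = union_tab("sequences"))
  attr(out, "collisions") <- collisions
  out
}

#' @export
print.mhdb <- function(x, ...) {
  cat("microhaplotype database:",
      nrow(x$markers), "markers,",
      nrow(x$populations), "populations,",
      nrow(x$frequencies), "frequency records\n")
  invisible(x)
}

#' @export
print.mh_marker <- function(x, ...) {
  cat(x$name, " (", x$chrom, "): ", length(x$positions), " SNPs, span ",
      min(x$positions), "-", max(x$positions), "\n", sep = "")
  invisible(x)
}
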