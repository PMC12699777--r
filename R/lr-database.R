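#' Ligand-receptor prior database
#'
#' An `lr_database` holds curated ligand-to-receptor binding pairs, each with a
#' dimensionless binding affinity in (0, 1] and a flag saying whether the pair
#' carries enough prior support (database curation) to induce a lower bound on
#' the corresponding communication flow.
#'
#' @param pairs A data frame with columns `ligand`, `receptor` and optionally
#'   `affinity` (numeric in (0, 1]) and `prior_confident` (logical or 0/1).
#' @param default_affinity Affinity assigned to rows lacking one. Must lie in
#'   (0, 1]; with the default 1 the affinity term of the edge cost is neutral
#'   and cost becomes purely distance-driven.
#' @param ignore_case Fold gene symbols to upper case before matching
#'   (convenient when mixing mouse and human symbol conventions).
#'
#' @return An object of class `lr_database`: a list with element `pairs`, a
#'   data frame sorted by (ligand, receptor) with exactly one row per pair.
#' @export
#' @examples
#' db <- lr_database(data.frame(ligand = "Psap", receptor = "Gpr37l1"))
#' binders(db, "Gpr37l1")
lr_database <- function(pairs, default_affinity = 1, ignore_case = FALSE) {
  if (!is.data.frame(pairs)) {
    stop("`pairs` must be a data frame", call. = FALSE)
  }
  for (col in c("ligand", "receptor")) {
    if (!col %in% names(pairs)) {
      stop(sprintf("ligand-receptor table is missing mandatory column '%s'", col),
           call. = FALSE)
    }
  }
  if (!is.numeric(default_affinity) || length(default_affinity) != 1 ||
      default_affinity <= 0 || default_affinity > 1) {
    stop("`default_affinity` must be a single number in (0, 1]", call. = FALSE)
  }
  lig <- trimws(as.character(pairs$ligand))
  rec <- trimws(as.character(pairs$receptor))
  if (ignore_case) {
    lig <- toupper(lig)
    rec <- toupper(rec)
  }
  if (any(!nzchar(lig)) || any(!nzchar(rec))) {
    bad <- which(!nzchar(lig) | !nzchar(rec))[1]
    stop(sprintf("empty gene symbol in row %d", bad), call. = FALSE)
  }
  if (length(lig) == 0) {
    stop("ligand-receptor table contains no pairs", call. = FALSE)
  }

  if ("affinity" %in% names(pairs)) {
    aff <- suppressWarnings(as.numeric(pairs$affinity))
    aff[is.na(pairs$affinity)] <- default_affinity
    bad <- which(is.na(aff) | aff <= 0 | aff > 1)
    if (length(bad) > 0) {
      stop(sprintf("affinity outside (0, 1] in row %d", bad[1]), call. = FALSE)
    }
  } else {
    aff <- rep(default_affinity, length(lig))
  }
  if ("prior_confident" %in% names(pairs)) {
    pc <- parse_flag(pairs$prior_confident)
    if (anyNA(pc)) {
      stop(sprintf("unparseable prior_confident value in row %d",
                   which(is.na(pc))[1]), call. = FALSE)
    }
  } else {
    pc <- rep(TRUE, length(lig))
  }

  df <- data.frame(ligand = lig, receptor = rec, affinity = aff,
                   prior_confident = pc, stringsAsFactors = FALSE)
  # duplicate (ligand, receptor) rows collapse to max affinity; prior support
  # is the OR over duplicates
  key <- paste(df$ligand, df$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    df <- do.call(rbind, lapply(split(df, key), function(g) {
      data.frame(ligand = g$ligand[1], receptor = g$receptor[1],
                 affinity = max(g$affinity),
                 prior_confident = any(g$prior_confident),
                 stringsAsFactors = FALSE)
    }))
  }
  df <- df[order(df$ligand, df$receptor), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(pairs = df), class = "lr_database")
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes")] <- TRUE
  out[s %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a ligand-receptor database from a delimited file
#'
#' Accepts comma- or tab-delimited text (auto-detected from the header line)
#' with a header row and columns `ligand,receptor[,affinity][,prior_confident]`,
#' the shape of flattened CellPhoneDB/CellChat-style exports. Multi-subunit
#' receptor complexes are not modeled: complexes must be pre-flattened to
#' single gene symbols upstream.
#'
#' @param path Path to the delimited file.
#' @inheritParams lr_database
#' @return An [lr_database()].
#' @export
read_lr_database <- function(path, default_affinity = 1, ignore_case = FALSE) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0) {
    stop(sprintf("'%s' contains no ligand-receptor pairs", path), call. = FALSE)
  }
  lr_database(df, default_affinity = default_affinity,
              ignore_case = ignore_case)
}

#' Write a ligand-receptor database as CSV
#'
#' @param db An [lr_database()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lr_database <- function(db, path) {
  stopifnot(inherits(db, "lr_database"))
  write_table_lf(db$pairs, path, sep = ",")
  invisible(path)
}

#' Ligands binding a receptor
#'
#' Returns the ligands that can bind `receptor` according to the prior
#' database, in deterministic lexicographic ligand order. Unknown receptors
#' yield an empty table rather than an error.
#'
#' @param db An [lr_database()].
#' @param receptor A receptor gene symbol.
#' @return A data frame with columns `ligand`, `affinity`, `prior_confident`.
#' @export
binders <- function(db, receptor) {
  stopifnot(inherits(db, "lr_database"), length(receptor) == 1)
  out <- db$pairs[db$pairs$receptor == receptor,
                  c("ligand", "affinity", "prior_confident"), drop = FALSE]
  out <- out[order(out$ligand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @exportS3Method base::print
print.lr_database <- function(x, ...) {
  cat(sprintf("<lr_database> %d pairs, %d ligands, %d receptors\n",
              nrow(x$pairs), length(unique(x$pairs$ligand)),
              length(unique(x$pairs$receptor))))
  invisible(x)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (length(header) == 0) stop(sprintf("'%s' is empty", path), call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

# Deterministic table writer: header, given separator, LF endings, numbers at
# 6 significant digits so repeated runs are byte-identical.
write_table_lf <- function(df, path, sep = "\t") {
  fmt_col <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.6g", x)
    else as.character(x)
  }
  cols <- lapply(df, fmt_col)
  lines <- c(paste(names(df), collapse = sep),
             if (nrow(df) > 0) do.call(paste, c(cols, sep = sep)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
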