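#' Read an expression matrix
#'
#' Accepts either a dense delimited table (header row of gene symbols, first
#' column of cell ids; comma or tab auto-detected) or a Matrix Market triplet
#' directory containing one `.mtx` file plus a gene list (`genes*` or
#' `features*`) and a barcode list (`barcodes*`), one id per line. Matrix
#' Market input shaped genes x cells (the 10x convention) is transposed so
#' cells are rows; orientation is detected by matching dimensions against
#' the id files.
#'
#' @param path File (dense) or directory (Matrix Market triplet).
#' @return Numeric matrix, cells in rows, genes in columns, nonnegative.
#' @export
read_expression <- function(path) {
  expr <- if (dir.exists(path)) read_expression_mtx(path)
          else read_expression_dense(path)
  validate_expression(expr)
}

read_expression_dense <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  cells <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
  rownames(m) <- cells
  m
}

read_expression_mtx <- function(path) {
  files <- list.files(path, full.names = TRUE)
  mtx <- files[grepl("\\.mtx$", files)]
  genes_f <- files[grepl("genes|features", basename(files), ignore.case = TRUE)]
  bc_f <- files[grepl("barcodes", basename(files), ignore.case = TRUE)]
  if (length(mtx) != 1 || length(genes_f) < 1 || length(bc_f) < 1) {
    stop("Matrix Market directory needs one .mtx file, a genes/features list ",
         "and a barcodes list", call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(mtx))
  read_ids <- function(f) {
    first <- utils::read.table(f, sep = detect_sep(f), header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    as.character(first)
  }
  genes <- read_ids(genes_f[1])
  cells <- read_ids(bc_f[1])
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- t(m)                               # genes x cells -> cells x genes
  } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
    stop("matrix dimensions match neither genes x cells nor cells x genes",
         call. = FALSE)
  }
  dimnames(m) <- list(cells, genes)
  m
}

#' Write an expression matrix as a dense CSV
#'
#' @param expr Numeric matrix, cells in rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(cell = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_lf(df, path, sep = ",")
}

#' Read a coordinate table
#'
#' Delimited text with columns `cell`, `x`, `y`.
#'
#' @param path Input path.
#' @return Data frame `cell,x,y`.
#' @export
read_coords <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("cell", "x", "y") %in% names(df))) {
    stop("coordinate table must have columns cell, x, y", call. = FALSE)
  }
  df$cell <- as.character(df$cell)
  validate_coords(df[, c("cell", "x", "y")])
}

#' Write a coordinate table as CSV
#'
#' @param coords Data frame `cell,x,y`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(coords, path) {
  validate_coords(coords)
  write_table_lf(coords[, c("cell", "x", "y")], path, sep = ",")
}

#' Read / write tab-separated flow tables
#'
#' Flow tables (edge-level, ligand-level, relay-level) are TSV with a header,
#' UTF-8, LF line endings, numbers at 6 significant digits, so repeated runs
#' are byte-identical.
#'
#' @param table A data frame.
#' @param path File path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_flow_table <- function(table, path) {
  write_table_lf(table, path, sep = "\t")
}

#' @rdname write_flow_table
#' @export
read_flow_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full inference pipeline
#'
#' Reads inputs (or takes them as objects), builds the receptor-centric flow
#' graph, solves the bounded circulation, redistributes flows to ligand
#' resolution, enumerates two-step relays, and writes `edge_flows.tsv`,
#' `ligand_flows.tsv`, `relays.tsv` and `manifest.json` into `out_dir`. On
#' infeasibility without `relax_lower`, writes `infeasible.tsv` with the
#' per-node shortfalls and raises an error.
#'
#' @param expression Expression matrix or path (see [read_expression()]).
#' @param coords Coordinate data frame or path.
#' @param db An [lr_database()] or path.
#' @param out_dir Output directory (created if absent).
#' @param config A [flow_config()].
#' @param seed Integer recorded in the manifest (inference itself is
#'   deterministic).
#' @param relax_lower Halve lower bounds on infeasibility (see
#'   [solve_flow()]).
#' @param verify Cross-check the solve against [lp_oracle()] on graphs up to
#'   500 edges.
#' @param min_flow Relay flow threshold.
#' @param gamma Affinity exponent for redistribution.
#' @return The manifest list, invisibly.
#' @export
run_infer <- function(expression, coords, db, out_dir, config,
                      seed = 1L, relax_lower = FALSE, verify = FALSE,
                      min_flow = 0, gamma = 1) {
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(coords)) coords <- read_coords(coords)
  if (is.character(db)) db <- read_lr_database(db)
  stopifnot(inherits(config, "flow_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  graph <- build_flow_graph(expression, coords, db, config)
  sol <- solve_flow(graph, relax_lower = relax_lower, verify = verify)
  if (!sol$feasible) {
    write_flow_table(sol$diagnostics, file.path(out_dir, "infeasible.tsv"))
    stop(sprintf("bounded circulation infeasible (%d node shortfalls); see %s",
                 nrow(sol$diagnostics), file.path(out_dir, "infeasible.tsv")),
         call. = FALSE)
  }
  lig <- split_flows(sol, expression, db, gamma = gamma, config = config)
  relays <- enumerate_relays(lig, min_flow = min_flow)

  write_flow_table(sol$flows, file.path(out_dir, "edge_flows.tsv"))
  write_flow_table(lig, file.path(out_dir, "ligand_flows.tsv"))
  write_flow_table(relays, file.path(out_dir, "relays.tsv"))

  manifest <- list(
    package = "flowccc",
    version = as.character(utils::packageVersion("flowccc")),
    seed = as.integer(seed),
    config = unclass(config),
    relax_lower = relax_lower,
    epsilon_factor = sol$epsilon_factor,
    n_cells = nrow(graph$nodes),
    n_edges = nrow(graph$edges),
    n_ligand_flows = nrow(lig),
    n_relays = nrow(relays),
    objective = sol$objective,
    feasible = sol$feasible)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
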