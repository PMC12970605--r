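#' Read a cells-by-features matrix from disk
#'
#' Loads a dense matrix from delimited text (CSV/TSV) or MatrixMarket (MTX;
#' densified on load, since the method operates on dense kernels). For
#' CSV/TSV, the first row may hold feature names and the first column cell
#' names, controlled by explicit flags (the common single-cell export
#' convention; flags avoid guessing). For MTX, optional sidecar name files
#' `<stem>_rows.txt` / `<stem>_cols.txt` are picked up when present. Any
#' NA/NaN/Inf entry is a validation error.
#'
#' @param path file path.
#' @param format `"csv"`, `"tsv"` or `"mtx"` (default guessed from the
#'   extension).
#' @param transpose set when the file stores features as rows; the returned
#'   object is always cells x features.
#' @param header first row holds feature names (CSV/TSV only).
#' @param rowNames first column holds cell names (CSV/TSV only).
#' @param maxCellsWarn warn above this cell count about the O(n^2) kernel
#'   cost.
#' @return A [ModalityData-class] object.
#' @export
readMatrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                       transpose = FALSE, header = TRUE, rowNames = TRUE,
                       maxCellsWarn = 5000L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    rn <- paste0(stem, "_rows.txt"); cn <- paste0(stem, "_cols.txt")
    if (file.exists(rn)) rownames(m) <- readLines(rn, warn = FALSE)
    if (file.exists(cn)) colnames(m) <- readLines(cn, warn = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    dt <- tryCatch(
      data.table::fread(path, sep = sep, header = header, data.table = FALSE),
      error = function(e) stop("malformed ", format, " file '", path, "': ",
                               conditionMessage(e)))
    if (rowNames) {
      rn <- as.character(dt[[1]])
      dt <- dt[, -1, drop = FALSE]
    } else rn <- NULL
    m <- as.matrix(dt)
    if (!is.numeric(m)) {
      bad <- which(!vapply(dt, is.numeric, logical(1)))[1]
      stop("non-numeric column ", bad, " in '", path, "'")
    }
    rownames(m) <- rn
  }
  storage.mode(m) <- "double"
  if (transpose) m <- t(m)
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite entry at row %d, column %d of '%s'",
                 bad[1], bad[2], path))
  }
  if (nrow(m) > maxCellsWarn)
    warning(sprintf(paste0("%d cells: dense %d x %d kernels are O(n^2) in ",
                           "memory and time"), nrow(m), nrow(m), nrow(m)))
  ModalityData(m)
}

#' Read per-cell labels from a plain text file
#'
#' One label token per line; blank lines are skipped.
#'
#' @param path file path.
#' @return character vector of labels.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lab <- trimws(readLines(path, warn = FALSE))
  lab <- lab[nzchar(lab)]
  if (!length(lab)) stop("label file '", path, "' contains no labels")
  lab
}

#' Write the outputs of an integration run
#'
#' Writes a deterministic file layout into `outdir`: `embeddings_x.csv` /
#' `embeddings_y.csv` (cells x k), `plan.csv`, `importance_x.csv` /
#' `importance_y.csv` (latent dims x features), `coclusters.csv` (cell id,
#' domain, cluster or `"pruned"`), `metrics.json`, `config.yaml` and
#' `run.log` (the training trace). All floats are printed with 17 significant
#' digits so a write/read round trip is bitwise exact. Only the components
#' actually supplied are written.
#'
#' @param outdir output directory (created; its parent must exist).
#' @param model optional trained [OTIntegration-class] (writes embeddings,
#'   config and log).
#' @param plan optional [TransportPlan-class].
#' @param importanceX,importanceY optional [ImportanceMatrix-class] objects.
#' @param coclusters optional [CoClustering-class].
#' @param metrics optional named list of metric values.
#' @param config optional configuration list (overrides the model's).
#' @return (invisibly) the manifest: a data.frame of written files with their
#'   shapes, also saved as `manifest.csv`.
#' @export
writeResults <- function(outdir, model = NULL, plan = NULL,
                         importanceX = NULL, importanceY = NULL,
                         coclusters = NULL, metrics = NULL, config = NULL) {
  if (!dir.exists(dirname(outdir)))
    stop("parent directory does not exist: ", dirname(outdir))
  dir.create(outdir, showWarnings = FALSE)
  manifest <- list()
  note <- function(file, obj) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file,
      rows = if (is.matrix(obj) || is.data.frame(obj)) nrow(obj) else length(obj),
      cols = if (is.matrix(obj) || is.data.frame(obj)) ncol(obj) else 1L)
  }
  writeNum <- function(m, file) {
    out <- file.path(outdir, file)
    fm <- apply(m, 2, function(col) sprintf("%.17g", col))
    dimnames(fm) <- dimnames(m)
    utils::write.table(fm, out, sep = ",", quote = FALSE,
                       row.names = !is.null(rownames(m)),
                       col.names = if (is.null(colnames(m))) FALSE else NA)
    note(file, m)
  }

  if (!is.null(model)) {
    writeNum(latentEmbedding(model, "x"), "embeddings_x.csv")
    writeNum(latentEmbedding(model, "y"), "embeddings_y.csv")
    if (is.null(config)) config <- model@config
    utils::write.csv(model@trace, file.path(outdir, "run.log"),
                     row.names = FALSE)
    note("run.log", model@trace)
  }
  if (!is.null(plan)) writeNum(planMatrix(plan), "plan.csv")
  if (!is.null(importanceX))
    writeNum(importanceScores(importanceX), "importance_x.csv")
  if (!is.null(importanceY))
    writeNum(importanceScores(importanceY), "importance_y.csv")
  if (!is.null(coclusters)) {
    asg <- clusterAssignments(coclusters)
    cc <- data.frame(
      cell = c(seq_along(asg$rows), seq_along(asg$cols)),
      domain = rep(c("x", "y"), c(length(asg$rows), length(asg$cols))),
      cluster = ifelse(is.na(c(asg$rows, asg$cols)), "pruned",
                       c(asg$rows, asg$cols)))
    utils::write.csv(cc, file.path(outdir, "coclusters.csv"),
                     row.names = FALSE)
    note("coclusters.csv", cc)
  }
  if (!is.null(metrics)) {
    jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    note("metrics.json", metrics)
  }
  if (!is.null(config)) {
    cfgOut <- lapply(config, function(v)
      if (is.numeric(v) && length(v) == 1 && is.infinite(v)) ".inf" else v)
    yaml::write_yaml(cfgOut, file.path(outdir, "config.yaml"))
    note("config.yaml", config)
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
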