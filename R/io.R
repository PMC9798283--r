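#' Read and write connectome matrices as CSV
#'
#' Dense CSV with a header row of region labels; SC and PL are stored in two
#' files sharing a prefix (\code{<prefix>_sc.csv}, \code{<prefix>_pl.csv}).
#'
#' @param connectome a \linkS4class{StructuralConnectome}.
#' @param prefix file path prefix.
#' @return \code{readConnectomeCSV} returns a
#'   \linkS4class{StructuralConnectome}; the writer returns the two paths
#'   invisibly.
#' @export
writeConnectomeCSV <- function(connectome, prefix) {
  labels <- sprintf("r%03d", seq_len(nRegions(connectome)))
  paths <- paste0(prefix, c("_sc.csv", "_pl.csv"))
  for (k in 1:2) {
    m <- if (k == 1) scMatrix(connectome) else plMatrix(connectome)
    colnames(m) <- labels
    write.csv(m, paths[k], row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname writeConnectomeCSV
#' @export
readConnectomeCSV <- function(prefix) {
  sc <- as.matrix(read.csv(paste0(prefix, "_sc.csv"), check.names = FALSE))
  pl <- as.matrix(read.csv(paste0(prefix, "_pl.csv"), check.names = FALSE))
  dimnames(sc) <- dimnames(pl) <- NULL
  new("StructuralConnectome", sc = sc, pl = pl)
}

#' Read and write BOLD time series as CSV
#'
#' Regions as rows, samples as columns; TR and band are carried in two
#' leading metadata columns.
#'
#' @param ts a \linkS4class{BoldTimeSeries}.
#' @param path CSV path.
#' @export
writeBoldCSV <- function(ts, path) {
  df <- data.frame(tr = repetitionTime(ts), band = bandName(ts),
                   tsValues(ts))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBoldCSV
#' @export
readBoldCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(vals) <- NULL
  new("BoldTimeSeries", values = vals, tr = df$tr[1],
      band = as.character(df$band[1]))
}

#' Read and write cohort metadata as CSV
#'
#' Columns: id, group, sex, age.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param path CSV path.
#' @export
writeCohortCSV <- function(cohort, path) {
  write.csv(subjectTable(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  makeCohort(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a synthetic-cohort configuration from YAML
#'
#' Any field of \code{\link{syntheticConfig}} may appear in the file;
#' unlisted fields keep their defaults.  \code{ageParams} and
#' \code{groundTruth} are nested maps with HC/PD entries.
#'
#' @param path YAML file.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
readConfigYAML <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  scalar <- c("nHC", "nPD", "ageFloor", "nRegions", "scDensity", "scMeanlog",
              "scDispersion", "measurementNoiseSd", "duration", "tr", "dt",
              "transient", "seed")
  for (f in scalar) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$plBounds)) args$plBounds <- as.numeric(unlist(raw$plBounds))
  if (!is.null(raw$maleProportion))
    args$maleProportion <- unlist(raw$maleProportion)
  if (!is.null(raw$ageParams))
    args$ageParams <- lapply(raw$ageParams, function(g)
      c(mean = g$mean, sd = g$sd))
  if (!is.null(raw$groundTruth))
    args$groundTruth <- lapply(raw$groundTruth, function(g)
      c(C = g$C, tau = g$tau))
  do.call(syntheticConfig, args)
}

#' Write a synthetic-cohort configuration to YAML
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param path output YAML file.
#' @export
writeConfigYAML <- function(config, path) {
  out <- list(nHC = config@nHC, nPD = config@nPD,
              ageParams = lapply(config@ageParams, function(g)
                list(mean = unname(g["mean"]), sd = unname(g["sd"]))),
              ageFloor = config@ageFloor,
              maleProportion = as.list(config@maleProportion),
              nRegions = config@nRegions, scDensity = config@scDensity,
              scMeanlog = config@scMeanlog,
              scDispersion = config@scDispersion,
              plBounds = config@plBounds,
              groundTruth = lapply(config@groundTruth, function(g)
                list(C = unname(g["C"]), tau = unname(g["tau"]))),
              measurementNoiseSd = config@measurementNoiseSd,
              duration = config@duration, tr = config@tr, dt = config@dt,
              transient = config@transient, seed = config@seed)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write prediction records as CSV
#'
#' @param records prediction-record data.frame from \code{\link{nestedCV}}.
#' @param path CSV path.
#' @export
writePredictionCSV <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
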