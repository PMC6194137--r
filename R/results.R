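#' Write stage outputs as tab-delimited tables with a run manifest
#'
#' Every table is written with a stable column order; association tables
#' are sorted by scaffold then position. A `manifest.tsv` records the run
#' configuration, seed, and an md5 checksum of every written file and of
#' the declared inputs, so reruns are verifiable byte-for-byte.
#'
#' @param tables Named list of `data.frame`s (name becomes
#'   `<name>.tsv`).
#' @param out_dir Output directory (created if needed).
#' @param config Optional named list of scalar configuration values.
#' @param seed Optional integer seed to record.
#' @param inputs Optional character vector of input file paths to checksum.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir, config = list(), seed = NULL,
                          inputs = character()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character()
  for (nm in names(tables)) {
    tb <- as.data.frame(tables[[nm]])
    if (all(c("scaffold", "pos") %in% names(tb)))
      tb <- tb[order(tb$scaffold, tb$pos), , drop = FALSE]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tb, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[nm] <- p
  }
  manifest <- data.frame(
    key = c(
      if (length(config)) paste0("config.", names(config)),
      if (!is.null(seed)) "seed",
      paste0("output.", names(paths)),
      if (length(inputs)) paste0("input.", basename(inputs))
    ),
    value = c(
      if (length(config)) vapply(config, function(x)
        paste(format(x, trim = TRUE), collapse = ","), character(1)),
      if (!is.null(seed)) as.character(seed),
      unname(md5sum(paths)),
      if (length(inputs)) unname(md5sum(inputs))
    ),
    stringsAsFactors = FALSE
  )
  mp <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["manifest"] <- mp
  invisible(paths)
}
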