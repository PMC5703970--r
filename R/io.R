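#' Read and write pipeline tables
#'
#' Plain-TSV readers/writers for the pipeline's tabular interfaces:
#' compound descriptor tables (`compound_id`, `name`, one column per
#' property, optional `dl_index`/`passed`), reference profiles
#' (`property`, `mean`, `sd`) and interaction tables. All numeric output
#' uses full precision so a written table re-read is exact.
#'
#' @param path file path.
#' @param compounds a [CompoundSet-class].
#' @param ref a [ReferenceProfile-class].
#' @param x a data.frame (interaction or pair table).
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeCompounds <- function(compounds, path) {
  tab <- asCompoundTable(compounds)
  if (all(is.na(tab$dl_index))) tab$dl_index <- NULL
  writeTSV(tab, path)
}

#' @rdname tableIO
#' @export
readCompounds <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  meta <- intersect(c("compound_id", "name", "dl_index", "passed"), names(tab))
  props <- setdiff(names(tab), meta)
  CompoundSet(ids = tab$compound_id,
              descriptors = as.matrix(tab[, props, drop = FALSE]),
              names = if ("name" %in% meta) tab$name else tab$compound_id,
              dlIndex = if ("dl_index" %in% meta) tab$dl_index else NULL)
}

#' @rdname tableIO
#' @export
writeReferenceProfile <- function(ref, path) {
  writeTSV(data.frame(property = ref@propertyNames, mean = ref@meanVector,
                      sd = ref@sdVector, stringsAsFactors = FALSE), path)
}

#' @rdname tableIO
#' @export
readReferenceProfile <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  ReferenceProfile(tab$property, tab$mean, tab$sd)
}

#' @rdname tableIO
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}
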