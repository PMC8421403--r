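# Checkpoint format: a directory holding header.json (dimensions, flags,
# gene ids, batch vocabulary, training config, array manifest), one raw
# little-endian double .bin file per named numeric array, and history.csv.
# Doubles round-trip bit-exactly through writeBin/readBin.

.flatten_arrays <- function(object) {
  p <- object$params
  arr <- list(alpha = p$alpha, rho = p$rho, lam = p$lam)
  for (nm in names(p$encoder)) arr[[paste0("enc.", nm)]] <- p$encoder[[nm]]
  if (!is.null(object$disc))
    for (nm in names(object$disc)) arr[[paste0("disc.", nm)]] <-
      object$disc[[nm]]
  arr
}

#' Save a fitted model to a checkpoint directory
#'
#' Writes a JSON header (dimensions, flags, gene identifiers, batch
#' vocabulary, configuration, array manifest), one binary array file per
#' parameter, and the training history as CSV. [read_sctopic()] restores
#' the model bit-exactly.
#'
#' @param object a fitted [sctopic] model.
#' @param dir checkpoint directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_sctopic <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- .flatten_arrays(object)
  manifest <- lapply(arr, function(a)
    list(dims = if (is.null(dim(a))) length(a) else dim(a)))
  p <- object$params
  header <- list(format = "sctopic-checkpoint-1",
                 K = p$K, L = p$L, V = p$V, S = p$S, H = p$H,
                 use_batch_intercept = p$use_batch_intercept,
                 rho_fixed = p$rho_fixed,
                 gene_ids = object$gene_ids,
                 batch_levels = object$batch_levels,
                 pathway_names = object$pathway_names,
                 config = object$config,
                 arrays = manifest)
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(arr)) {
    con <- file(file.path(dir, paste0(nm, ".bin")), "wb")
    writeBin(as.numeric(arr[[nm]]), con, size = 8L, endian = "little")
    close(con)
  }
  utils::write.csv(object$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir directory written by [write_sctopic()].
#' @return a fitted [sctopic] model object.
#' @export
read_sctopic <- function(dir) {
  hp <- file.path(dir, "header.json")
  if (!file.exists(hp)) .stopf("not a checkpoint directory: %s", dir)
  h <- jsonlite::read_json(hp, simplifyVector = TRUE)
  if (!identical(h$format, "sctopic-checkpoint-1"))
    .stopf("unrecognized checkpoint format")
  read_arr <- function(nm) {
    dims <- h$arrays[[nm]]$dims
    con <- file(file.path(dir, paste0(nm, ".bin")), "rb")
    on.exit(close(con))
    x <- readBin(con, "numeric", n = prod(dims), size = 8L,
                 endian = "little")
    if (length(dims) == 2L) dim(x) <- dims
    x
  }
  nms <- names(h$arrays)
  arr <- lapply(nms, read_arr)
  names(arr) <- nms
  enc <- arr[grepl("^enc\\.", nms)]
  names(enc) <- sub("^enc\\.", "", names(enc))
  disc <- NULL
  if (any(grepl("^disc\\.", nms))) {
    disc <- arr[grepl("^disc\\.", nms)]
    names(disc) <- sub("^disc\\.", "", names(disc))
  }
  params <- list(alpha = arr$alpha, rho = arr$rho, lam = arr$lam,
                 encoder = enc,
                 use_batch_intercept = h$use_batch_intercept,
                 rho_fixed = h$rho_fixed,
                 K = h$K, L = h$L, V = h$V, S = h$S, H = h$H)
  hist <- utils::read.csv(file.path(dir, "history.csv"))
  structure(list(params = params, disc = disc, history = hist,
                 gene_ids = h$gene_ids, batch_levels = h$batch_levels,
                 pathway_names = h$pathway_names,
                 config = h$config, call = NULL),
            class = "sctopic")
}
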