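#' @include pipeline-sim.R
NULL

.layerSpecToList <- function(sp) {
  list(kh = sp@kh, kw = sp@kw, cin = sp@cin, cout = sp@cout,
       stride = sp@stride, padding = sp@padding, hasBias = sp@hasBias,
       hasBN = sp@hasBN, activation = sp@activation, pool = sp@pool)
}

.layerSpecFromList <- function(x) {
  layerSpec(x$kh, x$kw, x$cin, x$cout, x$stride, x$padding, x$hasBias,
            x$hasBN, x$activation, x$pool)
}

#' Write / read a float model
#'
#' Portable plain-text container: one JSON document holding the layer
#' specs, class names, input dims, and all weight/bias/multiplier arrays
#' (flattened column-major with their dims).
#'
#' @param model a [FloatCNN-class]
#' @param file path to the JSON file
#' @return `writeFloatModel` invisibly returns `file`; `readFloatModel`
#'   returns the reconstructed [FloatCNN-class]
#' @export
writeFloatModel <- function(model, file) {
  doc <- list(
    container = "wbcquant-float-model", version = 1L,
    inputDim = model@inputDim, classNames = model@classNames,
    layers = lapply(model@layers, function(l) list(
      spec = .layerSpecToList(l$spec),
      W = list(dim = dim(l$W), data = as.vector(l$W)),
      b = l$b, m = l$m)))
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = I(17))
  invisible(file)
}

#' @rdname writeFloatModel
#' @export
readFloatModel <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = FALSE)
  layers <- lapply(doc$layers, function(l) {
    list(spec = .layerSpecFromList(l$spec),
         W = array(unlist(l$W$data), dim = unlist(l$W$dim)),
         b = as.numeric(unlist(l$b)),
         m = as.numeric(unlist(l$m)))
  })
  new("FloatCNN", layers = layers,
      inputDim = as.integer(unlist(doc$inputDim)),
      classNames = as.character(unlist(doc$classNames)))
}

#' Write / read a quantized model directory
#'
#' The directory holds `params.json` with every quantization constant
#' (layer specs, per-layer and per-kernel parameter triples, bias and
#' batch-norm constants) and one `weights_layerN.csv` per layer with the
#' integer kernel taps - all plain text, round-trippable bit-exactly.
#'
#' @param qmodel a [QuantizedModel-class]
#' @param dir directory to create/populate
#' @return `writeQuantizedModel` invisibly returns `dir`;
#'   `readQuantizedModel` returns the [QuantizedModel-class]
#' @export
writeQuantizedModel <- function(qmodel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doc <- list(
    container = "wbcquant-quantized-model", version = 1L,
    width = qmodel@cfg@width, inputDim = qmodel@inputDim,
    classNames = qmodel@classNames,
    inputParams = paramsToList(qmodel@inputParams),
    layers = lapply(seq_along(qmodel@layers), function(li) {
      l <- qmodel@layers[[li]]
      list(
        spec = .layerSpecToList(l$spec),
        inParams = paramsToList(l$inParams),
        tgtParams = paramsToList(l$tgtParams),
        outParams = paramsToList(l$outParams),
        kernels = lapply(l$kernels, function(k) list(
          wparams = paramsToList(k@wparams), oConv = k@oConv,
          sUni = k@sUni, nUni = k@nUni, oUni = k@oUni,
          qdim = dim(k@qweights))),
        bias = list(qb = l$bias@qb, sft = l$bias@sft,
                    addend = l$bias@addend, sb = l$bias@sb, nb = l$bias@nb),
        bn = if (is.null(l$bn)) NULL else list(qm = l$bn@qm, nm = l$bn@nm))
    }))
  jsonlite::write_json(doc, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  for (li in seq_along(qmodel@layers)) {
    taps <- vapply(qmodel@layers[[li]]$kernels,
                   function(k) as.vector(k@qweights),
                   numeric(length(qmodel@layers[[li]]$kernels[[1]]@qweights)))
    utils::write.csv(as.data.frame(taps),
                     file.path(dir, sprintf("weights_layer%d.csv", li)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeQuantizedModel
#' @export
readQuantizedModel <- function(dir) {
  doc <- jsonlite::read_json(file.path(dir, "params.json"),
                             simplifyVector = FALSE)
  cfg <- bitWidthConfig(doc$width)
  layers <- lapply(seq_along(doc$layers), function(li) {
    l <- doc$layers[[li]]
    taps <- utils::read.csv(file.path(dir, sprintf("weights_layer%d.csv", li)))
    kernels <- lapply(seq_along(l$kernels), function(ki) {
      k <- l$kernels[[ki]]
      kernelQuant(array(taps[[ki]], dim = unlist(k$qdim)),
                  paramsFromList(k$wparams), k$oConv, k$sUni, k$nUni, k$oUni)
    })
    list(spec = .layerSpecFromList(l$spec),
         inParams = paramsFromList(l$inParams),
         kernels = kernels,
         tgtParams = paramsFromList(l$tgtParams),
         bias = biasQuant(unlist(l$bias$qb), l$bias$sft,
                          unlist(l$bias$addend), l$bias$sb, l$bias$nb),
         bn = if (is.null(l$bn)) NULL
              else bnQuant(unlist(l$bn$qm), l$bn$nm),
         outParams = paramsFromList(l$outParams))
  })
  new("QuantizedModel", layers = layers,
      inputParams = paramsFromList(doc$inputParams), cfg = cfg,
      classNames = unlist(doc$classNames),
      inputDim = as.integer(unlist(doc$inputDim)))
}

#' Write a cell image set to a directory of PNGs plus a JSON manifest
#'
#' Images and masks become 8-bit grayscale PNGs; the manifest records
#' paths, labels, split tags, the master seed and the generator
#' parameters, so a run is fully reconstructable.
#'
#' @param dataset a [CellImageSet-class]
#' @param dir output directory
#' @return invisibly, the manifest path
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset@images)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    imgFile <- sprintf("img_%04d.png", i)
    maskFile <- sprintf("mask_%04d.png", i)
    png::writePNG(dataset@images[[i]], file.path(dir, imgFile))
    png::writePNG(dataset@masks[[i]], file.path(dir, maskFile))
    entries[[i]] <- list(image = imgFile, mask = maskFile,
                         label = dataset@labels[i], split = dataset@split[i])
  }
  manifest <- list(container = "wbcquant-dataset", version = 1L,
                   seed = dataset@seed, params = dataset@params,
                   classNames = c("lymphocyte", "monocyte", "neutrophil"),
                   entries = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a cell image set written by [writeDataset()]
#'
#' @param dir dataset directory containing `manifest.json`
#' @return a [CellImageSet-class]
#' @export
loadDataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  n <- length(man$entries)
  images <- vector("list", n); masks <- vector("list", n)
  labels <- integer(n); split <- character(n)
  for (i in seq_len(n)) {
    e <- man$entries[[i]]
    images[[i]] <- .readGrayPNG(file.path(dir, e$image))
    masks[[i]] <- (.readGrayPNG(file.path(dir, e$mask)) > 0.5) * 1
    labels[i] <- e$label
    split[i] <- e$split
  }
  new("CellImageSet", images = images, masks = masks, labels = labels,
      split = split, seed = as.integer(man$seed),
      params = lapply(man$params, unlist))
}

#' Read a grayscale image file (PNG)
#'
#' @param file PNG path; color images are averaged to one channel
#' @return numeric matrix in \[0, 1\]
#' @export
readCellImage <- function(file) .readGrayPNG(file)

.readGrayPNG <- function(file) {
  x <- png::readPNG(file)
  if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3L, dim(x)[3])),
                                         drop = FALSE], c(1, 2), mean)
  x
}

#' Serialize an evaluation report to a plain list / JSON file
#'
#' @param report an [EvalReport-class]
#' @param file optional JSON path
#' @return the report as a plain list (invisibly when `file` is given)
#' @export
reportToJSON <- function(report, file = NULL) {
  x <- list(overall = report@overall, perClass = as.list(report@perClass),
            confusion = unclass(report@confusion),
            accuracyDrop = report@accuracyDrop)
  if (!is.null(file)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
    return(invisible(x))
  }
  x
}
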