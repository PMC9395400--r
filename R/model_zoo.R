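# Architecture definitions and the analytic parameter-budget oracle.

.layerRow <- function(kind, n_in, n_out, kernel = NA_integer_, bias = FALSE) {
  data.frame(kind = kind, "in" = as.integer(n_in), out = as.integer(n_out),
             kernel = as.integer(kernel), bias = bias,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# conv (3x3, same padding) + batch norm + ReLU
.convBNRelu <- function(n_in, n_out, kernel = 3L) {
  rbind(.layerRow("conv", n_in, n_out, kernel, bias = TRUE),
        .layerRow("batch_norm", n_out, n_out),
        .layerRow("activation", n_out, n_out))
}

# The 13-conv VGG16 trunk with batch norm and five 2x2 max-pools.
.vggTrunk <- function() {
  cfg <- list(c(3L, 64L), c(64L, 64L), "M",
              c(64L, 128L), c(128L, 128L), "M",
              c(128L, 256L), c(256L, 256L), c(256L, 256L), "M",
              c(256L, 512L), c(512L, 512L), c(512L, 512L), "M",
              c(512L, 512L), c(512L, 512L), c(512L, 512L), "M")
  out <- list()
  ch <- 3L
  for (item in cfg) {
    if (identical(item, "M")) {
      out[[length(out) + 1L]] <- .layerRow("max_pool", ch, ch, 2L)
    } else {
      out[[length(out) + 1L]] <- .convBNRelu(item[1], item[2])
      ch <- item[2]
    }
  }
  do.call(rbind, out)
}

# Walk the layer table tracking (channels, height, width); stop with an
# error on any incompatibility. Returns the final shape.
.specWalkShapes <- function(spec) {
  layers <- spec@layers
  if (nrow(layers) == 0) stop("architecture has no layers")
  ch <- layers[["in"]][1]
  h <- w <- spec@inputSize
  spatial <- TRUE
  for (i in seq_len(nrow(layers))) {
    kind <- layers$kind[i]
    n_in <- layers[["in"]][i]
    n_out <- layers$out[i]
    if (!kind %in% .LAYER_KINDS)
      stop("unsupported layer kind: ", kind)
    if (kind %in% c("conv", "fully_connected") &&
        (is.na(n_in) || is.na(n_out) || n_in < 1L || n_out < 1L))
      stop(kind, " layer needs positive in/out channels (layer ", i, ")")
    switch(kind,
      conv = {
        if (!spatial) stop("conv after spatial dimensions collapsed")
        if (n_in != ch) stop("conv layer ", i, " expects ", n_in,
                             " channels, gets ", ch)
        k <- layers$kernel[i]
        if (is.na(k) || k < 1L || k %% 2L == 0L)
          stop("conv kernel must be a positive odd edge length (layer ", i, ")")
        ch <- n_out
      },
      batch_norm = ,
      activation = {
        if (n_in != ch || n_out != ch)
          stop(kind, " layer ", i, " must preserve ", ch, " channels")
      },
      max_pool = {
        if (!spatial) stop("max_pool after spatial dimensions collapsed")
        if (h %% 2L != 0L || w %% 2L != 0L)
          stop("max_pool layer ", i, " needs even spatial dims, has ",
               h, "x", w)
        h <- h %/% 2L
        w <- w %/% 2L
        if (h < 1L || w < 1L)
          stop("input too small for the pooling cascade")
      },
      global_avg_pool = {
        if (!spatial) stop("global_avg_pool applied twice")
        h <- w <- 1L
        spatial <- FALSE
      },
      fully_connected = {
        feat <- if (spatial) ch * h * w else ch
        if (n_in != feat)
          stop("fully_connected layer ", i, " expects ", n_in,
               " features, gets ", feat)
        ch <- n_out
        h <- w <- 1L
        spatial <- FALSE
      })
  }
  last <- layers[nrow(layers), ]
  if (!(last$kind == "fully_connected" && last$out == spec@numClasses))
    stop("final layer must be fully_connected emitting numClasses outputs")
  list(channels = ch, height = h, width = w)
}

.newSpec <- function(name, layers, numClasses, inputSize) {
  rownames(layers) <- NULL
  new("ArchitectureSpec", name = name, layers = layers,
      numClasses = as.integer(numClasses), inputSize = as.integer(inputSize))
}

#' The VGG_NIN screening network
#'
#' The VGG16-with-batch-norm convolutional trunk (13 conv layers, 5
#' max-pools) whose three fully connected layers are replaced,
#' network-in-network style, by two 1x1 convolutions (512 -> 2048 and
#' 2048 -> 2048, each with bias, batch norm and ReLU), global average
#' pooling, and a single 2048 -> \code{numClasses} linear head. For two
#' classes this totals 19,982,402 trainable parameters versus 134,277,186
#' for the VGG16-bn baseline.
#'
#' @param numClasses number of output classes (>= 2).
#' @param inputSize input edge length in pixels; must be a multiple of 32
#'   (five 2x2 pools). Default 224.
#' @return an \linkS4class{ArchitectureSpec}.
#' @seealso \code{\link{vgg16bnSpec}}, \code{\link{parameterBudget}}
#' @examples
#' parameterBudget(vggNinSpec(2))
#' @export
vggNinSpec <- function(numClasses = 2L, inputSize = 224L) {
  if (numClasses < 2L) stop("numClasses must be >= 2")
  layers <- rbind(
    .vggTrunk(),
    .convBNRelu(512L, 2048L, kernel = 1L),
    .convBNRelu(2048L, 2048L, kernel = 1L),
    .layerRow("global_avg_pool", 2048L, 2048L),
    .layerRow("fully_connected", 2048L, numClasses, bias = TRUE))
  .newSpec("VGG_NIN", layers, numClasses, inputSize)
}

#' The VGG16-bn baseline network
#'
#' Standard VGG16 with batch normalization: the 13-conv trunk followed by
#' the classic three-layer fully connected head
#' (25088 -> 4096 -> 4096 -> \code{numClasses}, all with bias and ReLU
#' between). Dropout carries no parameters and is omitted.
#'
#' @inheritParams vggNinSpec
#' @return an \linkS4class{ArchitectureSpec}.
#' @examples
#' parameterBudget(vgg16bnSpec(2))
#' @export
vgg16bnSpec <- function(numClasses = 2L, inputSize = 224L) {
  if (numClasses < 2L) stop("numClasses must be >= 2")
  feat <- as.integer(512L * (inputSize %/% 32L)^2)
  layers <- rbind(
    .vggTrunk(),
    .layerRow("fully_connected", feat, 4096L, bias = TRUE),
    .layerRow("activation", 4096L, 4096L),
    .layerRow("fully_connected", 4096L, 4096L, bias = TRUE),
    .layerRow("activation", 4096L, 4096L),
    .layerRow("fully_connected", 4096L, numClasses, bias = TRUE))
  .newSpec("VGG16_bn", layers, numClasses, inputSize)
}

#' A desk-scale reference network in the VGG_NIN topology family
#'
#' A small network preserving the screening architecture's design pattern
#' (conv trunk, two 1x1 convolutions, global average pooling, linear
#' head) but sized to train on one CPU in minutes: conv 3->16 and 16->32
#' (each with batch norm, ReLU and a 2x2 max-pool), 1x1 convs 32->64 and
#' 64->64, global average pool, linear 64 -> \code{numClasses}. Under
#' 12,000 parameters.
#'
#' @param inputSize input edge length in pixels (>= 16, multiple of 4).
#' @param numClasses number of output classes (>= 2).
#' @return an \linkS4class{ArchitectureSpec}.
#' @examples
#' parameterBudget(smallReferenceSpec(32, 2))
#' @export
smallReferenceSpec <- function(inputSize = 32L, numClasses = 2L) {
  if (inputSize < 16L)
    stop("inputSize must be >= 16 for the pooling cascade")
  if (inputSize %% 4L != 0L)
    stop("inputSize must be a multiple of 4 (two 2x2 max-pools)")
  if (numClasses < 2L) stop("numClasses must be >= 2")
  layers <- rbind(
    .convBNRelu(3L, 16L),
    .layerRow("max_pool", 16L, 16L, 2L),
    .convBNRelu(16L, 32L),
    .layerRow("max_pool", 32L, 32L, 2L),
    .convBNRelu(32L, 64L, kernel = 1L),
    .convBNRelu(64L, 64L, kernel = 1L),
    .layerRow("global_avg_pool", 64L, 64L),
    .layerRow("fully_connected", 64L, numClasses, bias = TRUE))
  .newSpec("small_reference", layers, numClasses, inputSize)
}

.layerParamCount <- function(row) {
  switch(row$kind,
    conv = row[["in"]] * row$out * row$kernel^2 + if (row$bias) row$out else 0,
    batch_norm = 2 * row$out,
    fully_connected = row[["in"]] * row$out + if (row$bias) row$out else 0,
    0)
}

#' @rdname parameterBudget
#' @export
setMethod("parameterBudget", "ArchitectureSpec", function(object) {
  .specWalkShapes(object)  # errors on incompatible specs
  sum(vapply(seq_len(nrow(object@layers)),
             function(i) .layerParamCount(object@layers[i, ]), numeric(1)))
})

#' Plain-text layer table for an architecture
#'
#' One row per layer with its kind, channel fan-in/out, kernel edge, bias
#' flag and analytic parameter count. Round-trips through
#' \code{\link{architectureFromTable}} so architectures can be diffed and
#' stored as text.
#'
#' @param spec an \linkS4class{ArchitectureSpec}.
#' @return data.frame with columns kind, in, out, kernel, bias, params.
#' @export
layerTable <- function(spec) {
  stopifnot(is(spec, "ArchitectureSpec"))
  tab <- spec@layers
  tab$params <- vapply(seq_len(nrow(tab)),
                       function(i) .layerParamCount(tab[i, ]), numeric(1))
  rownames(tab) <- NULL
  tab
}

#' Rebuild an ArchitectureSpec from its layer table
#'
#' @param table a data.frame as produced by \code{\link{layerTable}} (the
#'   \code{params} column, if present, is ignored).
#' @param name architecture label.
#' @param numClasses,inputSize as in \code{\link{vggNinSpec}}.
#' @return an \linkS4class{ArchitectureSpec}.
#' @export
architectureFromTable <- function(table, name, numClasses, inputSize) {
  need <- c("kind", "in", "out", "kernel", "bias")
  if (!all(need %in% names(table)))
    stop("layer table must have columns: ", paste(need, collapse = ", "))
  layers <- data.frame(kind = as.character(table$kind),
                       "in" = as.integer(table[["in"]]),
                       out = as.integer(table$out),
                       kernel = as.integer(table$kernel),
                       bias = as.logical(table$bias),
                       check.names = FALSE, stringsAsFactors = FALSE)
  .newSpec(name, layers, numClasses, inputSize)
}
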