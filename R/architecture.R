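#' @include AllGenerics.R
NULL

#' Build the ensemble-member CNN architecture
#'
#' A VGG-style stack: five blocks of (2, 2, 4, 4, 4) convolution+ReLU layers
#' with 64/128/256/512/512 filters (3 x 3 kernels, stride 1, pad 1), each
#' block closed by a 2 x 2 stride-2 max-pool, followed by a 4096-unit fully
#' connected layer with ReLU and an `M`-way softmax output.  `scale`
#' multiplies all widths (filter counts and the fully-connected width) for
#' desk-scale runs.
#'
#' @param inputShape integer vector (H, W, C); H and W must be divisible
#'   by 2^5.
#' @param M number of classes.
#' @param scale width multiplier in (0, 1].
#' @return list with `layers` (layer descriptors), `inputShape`, `M`,
#'   `scale`; class `"CNNArchitecture"`.
#' @examples
#' arch <- buildArchitecture(c(64, 64, 3), M = 3, scale = 0.125)
#' length(arch$layers)
#' @export
buildArchitecture <- function(inputShape = c(224L, 224L, 3L), M = 3L,
                              scale = 1) {
  if (scale <= 0 || scale > 1) stop("'scale' must be in (0, 1]")
  if (length(inputShape) != 3L) stop("'inputShape' must be (H, W, C)")
  if (any(inputShape[1:2] %% 32L != 0L)) {
    stop("input height and width must be divisible by 2^5 = 32")
  }
  baseFilters <- c(64L, 128L, 256L, 512L, 512L)
  depths <- c(2L, 2L, 4L, 4L, 4L)
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  for (b in seq_along(depths)) {
    f <- max(1L, as.integer(round(scale * baseFilters[b])))
    for (i in seq_len(depths[b])) {
      add(list(kind = "conv", filters = f, kernel = 3L, stride = 1L, pad = 1L))
      add(list(kind = "relu"))
    }
    add(list(kind = "maxpool", kernel = 2L, stride = 2L, pad = 0L))
  }
  add(list(kind = "fc", units = max(1L, as.integer(round(scale * 4096L)))))
  add(list(kind = "relu"))
  add(list(kind = "fc", units = as.integer(M)))
  add(list(kind = "softmax"))
  structure(list(layers = layers, inputShape = as.integer(inputShape),
                 M = as.integer(M), scale = scale),
            class = "CNNArchitecture")
}

#' Propagate a shape through an architecture
#'
#' Convolutions and pools follow
#' `out = floor((in + 2 pad - kernel) / stride) + 1` per spatial dimension;
#' ReLU preserves shape; a fully connected layer flattens to its unit count.
#'
#' @param arch a `"CNNArchitecture"` (see [buildArchitecture()]).
#' @param inputShape (H, W, C); defaults to the architecture's own.
#' @return list of output shapes, one per layer (spatial layers as
#'   `c(H, W, C)`, dense layers as a single length).
#' @examples
#' arch <- buildArchitecture(c(224, 224, 3), M = 3)
#' shapePropagate(arch)[[5]]  # 112 112 64 after the first pool
#' @export
shapePropagate <- function(arch, inputShape = arch$inputShape) {
  shape <- as.integer(inputShape)
  out <- vector("list", length(arch$layers))
  for (li in seq_along(arch$layers)) {
    l <- arch$layers[[li]]
    shape <- switch(l$kind,
      conv = {
        sp <- (shape[1:2] + 2L * l$pad - l$kernel) %/% l$stride + 1L
        c(sp, l$filters)
      },
      relu = shape,
      maxpool = {
        sp <- (shape[1:2] + 2L * l$pad - l$kernel) %/% l$stride + 1L
        c(sp, shape[3])
      },
      fc = l$units,
      softmax = shape,
      stop("unknown layer kind: ", l$kind))
    if (any(shape <= 0L)) {
      stop(sprintf("layer %d (%s) yields a non-positive dimension", li, l$kind))
    }
    out[[li]] <- shape
  }
  out
}

#' @export
print.CNNArchitecture <- function(x, ...) {
  shapes <- shapePropagate(x)
  cat(sprintf("CNNArchitecture: input %s, %d layers, scale %.3g\n",
      paste(x$inputShape, collapse = "x"), length(x$layers), x$scale))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    extra <- if (l$kind == "conv") sprintf(" f=%d", l$filters)
             else if (l$kind == "fc") sprintf(" u=%d", l$units) else ""
    cat(sprintf("  %2d %-8s%-8s-> %s\n", i, l$kind, extra,
                paste(shapes[[i]], collapse = "x")))
  }
  invisible(x)
}
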