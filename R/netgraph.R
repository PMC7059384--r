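#' A single layer specification
#'
#' @param index 0-based layer index (topological order).
#' @param kind One of `"conv"`, `"maxpool"`, `"upsample"`, `"route"`,
#'   `"concat"`, `"detect"`.
#' @param filters Output channels (conv only).
#' @param kernel Kernel size (conv/maxpool).
#' @param stride Stride (maxpool) or scale factor (upsample).
#' @param sources 0-based indices of input layers for route/concat;
#'   all other kinds implicitly consume the previous layer.
#' @return A list of class `"layer_spec"`.
#' @export
layer_spec <- function(index, kind, filters = NA_integer_,
                       kernel = NA_integer_, stride = NA_integer_,
                       sources = NULL) {
  kind <- match.arg(kind, c("conv", "maxpool", "upsample", "route",
                            "concat", "detect"))
  structure(list(index = as.integer(index), kind = kind,
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 stride = as.integer(stride),
                 sources = if (!is.null(sources)) as.integer(sources)),
            class = "layer_spec")
}

#' Build the two-scale detection architecture graph
#'
#' Constructs the declarative layer graph of a tiny-YOLOv3-style
#' detector with two detection scales. The encoder is five
#' convolution-and-max-pooling blocks whose 3x3 convolutions start at 16
#' filters and double per block (16, 32, 64, 128, 256); the five
#' stride-2 pools downsample by a factor of 32 in total, so a 608x608
#' input reaches the end of the encoder at 19x19x256. A head of
#' convolutions (512, a 256 bottleneck, 512) leads to the coarse
#' detection layer; a route from the bottleneck passes through a
#' 128-filter 1x1 convolution and a 2x upsample, is concatenated with
#' the last encoder-block convolution output (38x38x256), and two
#' fusion convolutions produce the fine detection layer. Both detection
#' heads emit `anchors_per_scale * (5 + num_classes)` channels — the
#' 4 box coordinates, 1 objectness score and the class scores per
#' anchor slot.
#'
#' @param num_classes Number of object classes (>= 1).
#' @param anchors_per_scale Anchor slots per grid cell (>= 1).
#' @return An object of class `"arch_graph"`: list with `layers`
#'   (ordered [layer_spec()]s), `num_classes`, `anchors_per_scale`, and
#'   `notes` recording how the mid-head route was resolved.
#' @export
build_graph <- function(num_classes, anchors_per_scale = 3L) {
  num_classes <- as.integer(num_classes)
  anchors_per_scale <- as.integer(anchors_per_scale)
  if (is.na(num_classes) || num_classes < 1L)
    stop("num_classes must be a positive integer", call. = FALSE)
  if (is.na(anchors_per_scale) || anchors_per_scale < 1L)
    stop("anchors_per_scale must be a positive integer", call. = FALSE)
  det <- anchors_per_scale * (5L + num_classes)

  layers <- list()
  add <- function(kind, ...) {
    layers[[length(layers) + 1L]] <<-
      layer_spec(index = length(layers), kind = kind, ...)
  }
  # encoder: 5 blocks of (3x3 conv, 2x2 stride-2 maxpool), filters double
  filters <- 16L
  for (block in 1:5) {
    add("conv", filters = filters, kernel = 3L, stride = 1L)
    add("maxpool", kernel = 2L, stride = 2L)
    filters <- filters * 2L
  }
  # coarse head (indices 10-14)
  add("conv", filters = 512L, kernel = 3L, stride = 1L)   # 10
  add("conv", filters = 256L, kernel = 1L, stride = 1L)   # 11 mid-head bottleneck
  add("conv", filters = 512L, kernel = 3L, stride = 1L)   # 12
  add("conv", filters = det, kernel = 1L, stride = 1L)    # 13
  add("detect")                                           # 14 coarse scale
  # fine-scale tail: route from the bottleneck, 128-filter conv,
  # 2x upsample, concat with the last encoder-block conv (index 8)
  add("route", sources = 11L)                             # 15
  add("conv", filters = 128L, kernel = 1L, stride = 1L)   # 16
  add("upsample", stride = 2L)                            # 17
  add("concat", sources = c(17L, 8L))                     # 18
  add("conv", filters = 128L, kernel = 3L, stride = 1L)   # 19 fusion
  add("conv", filters = det, kernel = 1L, stride = 1L)    # 20 fusion
  add("detect")                                           # 21 fine scale

  graph <- structure(list(
    layers = layers, num_classes = num_classes,
    anchors_per_scale = anchors_per_scale,
    notes = paste("mid-head route resolved to the 256-filter bottleneck",
                  "conv at 0-based index 11; fine-scale concat joins the",
                  "upsampled features with encoder conv at index 8")
  ), class = "arch_graph")
  validate_graph(graph)
  graph
}

#' Assemble an architecture graph from layer specs
#'
#' Low-level constructor for custom graphs (e.g. ablations with a
#' different pool count); [build_graph()] produces the canonical
#' two-scale detector.
#'
#' @param layers Ordered list of [layer_spec()]s with 0-based indices.
#' @param num_classes,anchors_per_scale Head configuration.
#' @param notes Optional free-text provenance notes.
#' @return An `"arch_graph"` object.
#' @export
arch_graph <- function(layers, num_classes = 1L, anchors_per_scale = 1L,
                       notes = NULL) {
  graph <- structure(list(layers = layers,
                          num_classes = as.integer(num_classes),
                          anchors_per_scale = as.integer(anchors_per_scale),
                          notes = notes),
                     class = "arch_graph")
  validate_graph(graph)
  graph
}

validate_graph <- function(graph) {
  stopifnot(inherits(graph, "arch_graph"))
  idx <- vapply(graph$layers, `[[`, integer(1), "index")
  if (!identical(idx, seq_along(graph$layers) - 1L))
    stop("layer indices must be 0..n-1 in order", call. = FALSE)
  for (l in graph$layers) {
    if (l$kind %in% c("route", "concat")) {
      if (is.null(l$sources) || any(l$sources >= l$index) ||
          any(l$sources < 0L))
        stop(sprintf("layer %d: %s sources must precede the layer",
                     l$index, l$kind), call. = FALSE)
    }
  }
  invisible(graph)
}

#' Infer per-layer output shapes
#'
#' Propagates an input of spatial size `input_hw` (3 channels) through
#' the graph: same-padded convolutions preserve the spatial size,
#' stride-2 max pools halve it (floor), upsamples multiply it by their
#' factor, routes copy their source, concats sum channels and require
#' identical spatial sizes, detect layers pass shapes through. The input
#' side must be divisible by 32 so the two detection grids land on whole
#' cells.
#'
#' @param graph An [build_graph()] result (or compatible
#'   `"arch_graph"`).
#' @param input_hw Integer `c(H, W)`, each divisible by 32.
#' @return Data frame with one row per layer: `index`, `kind`,
#'   `height`, `width`, `channels`.
#' @export
infer_shapes <- function(graph, input_hw = c(608L, 608L)) {
  validate_graph(graph)
  input_hw <- as.integer(input_hw)
  stopifnot(length(input_hw) == 2L)
  if (any(input_hw %% 32L != 0L))
    stop(sprintf("input size %dx%d not divisible by 32",
                 input_hw[1], input_hw[2]), call. = FALSE)
  n <- length(graph$layers)
  H <- integer(n); W <- integer(n); C <- integer(n)
  shape_of <- function(i) {  # 0-based index; -1 = network input
    if (i < 0L) c(input_hw, 3L) else c(H[i + 1L], W[i + 1L], C[i + 1L])
  }
  for (l in graph$layers) {
    prev <- shape_of(l$index - 1L)
    s <- switch(l$kind,
      conv = c(prev[1], prev[2], l$filters),
      maxpool = c(prev[1] %/% l$stride, prev[2] %/% l$stride, prev[3]),
      upsample = c(prev[1] * l$stride, prev[2] * l$stride, prev[3]),
      route = shape_of(l$sources[1]),
      concat = {
        src <- lapply(l$sources, shape_of)
        hw <- vapply(src, function(x) x[1:2], integer(2))
        if (any(hw[1, ] != hw[1, 1]) || any(hw[2, ] != hw[2, 1]))
          stop(sprintf(
            "concat at layer %d: spatial mismatch among sources %s (%s)",
            l$index, paste(l$sources, collapse = ","),
            paste(apply(hw, 2, paste, collapse = "x"), collapse = " vs ")),
            call. = FALSE)
        c(src[[1]][1:2], sum(vapply(src, `[[`, integer(1), 3)))
      },
      detect = prev
    )
    H[l$index + 1L] <- s[1]; W[l$index + 1L] <- s[2]; C[l$index + 1L] <- s[3]
  }
  data.frame(index = seq_len(n) - 1L,
             kind = vapply(graph$layers, `[[`, character(1), "kind"),
             height = H, width = W, channels = C)
}

#' Total encoder downsampling factor
#'
#' Product of the strides of all pooling layers on the encoder path
#' (layers preceding the first detection head). The built two-scale
#' graph has five stride-2 pools, hence a factor of 32.
#'
#' @inheritParams infer_shapes
#' @return An integer.
#' @export
downsample_factor <- function(graph) {
  validate_graph(graph)
  kinds <- vapply(graph$layers, `[[`, character(1), "kind")
  first_detect <- match("detect", kinds, nomatch = length(kinds) + 1L)
  f <- 1L
  for (l in graph$layers) {
    if (l$index + 1L >= first_detect) break
    if (l$kind == "maxpool") f <- f * l$stride
  }
  f
}

#' Count trainable parameters of the convolutional layers
#'
#' Sums `kernel^2 * C_in * C_out + C_out` (weights plus biases) over all
#' convolution layers, with input channel counts obtained by shape
#' inference. Spatial input size does not affect the count.
#'
#' @inheritParams infer_shapes
#' @return An integer parameter count.
#' @export
parameter_count <- function(graph) {
  validate_graph(graph)
  shapes <- infer_shapes(graph, c(32L, 32L))
  total <- 0
  for (l in graph$layers) {
    if (l$kind != "conv") next
    c_in <- if (l$index == 0L) 3L else shapes$channels[l$index]
    total <- total + l$kernel^2 * c_in * l$filters + l$filters
  }
  as.integer(total)
}

#' @export
print.arch_graph <- function(x, ...) {
  cat(sprintf(
    "Two-scale detection graph: %d layers, %d classes, %d anchors/scale\n",
    length(x$layers), x$num_classes, x$anchors_per_scale))
  tab <- format_graph(x)
  cat(paste(tab, collapse = "\n"), "\n")
  invisible(x)
}

#' Plain-text layer table of a graph
#'
#' @inheritParams infer_shapes
#' @return Character vector, one line per layer
#'   (`index kind filters kernel stride sources`).
#' @export
format_graph <- function(graph) {
  validate_graph(graph)
  vapply(graph$layers, function(l) {
    sprintf("%3d  %-8s f=%-4s k=%-2s s=%-2s %s",
            l$index, l$kind,
            ifelse(is.na(l$filters), "-", l$filters),
            ifelse(is.na(l$kernel), "-", l$kernel),
            ifelse(is.na(l$stride), "-", l$stride),
            if (is.null(l$sources)) ""
            else paste0("<- ", paste(l$sources, collapse = ",")))
  }, character(1))
}
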