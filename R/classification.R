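#' Architecture specification of the compact species classifier
#'
#' The classifier family has four convolutional layers, each followed by
#' 2x2 stride-2 max pooling, then one hidden dense layer and a 10-way
#' softmax output. The two middle convolutions are fixed at 64 kernels of
#' 3x3; the first and last convolution and the dense width are the tunable
#' hyperparameters explored by the architecture grid. All convolutions are
#' zero-padded to preserve spatial size ('same' padding) and use ReLU, so a
#' 128x128 input reaches the flatten stage at 8x8 after the four poolings.
#'
#' @param kernel_first,kernel_last Kernel side of the first/last convolution
#'   (one of 1, 3, 5).
#' @param depth_first,depth_last Number of kernels in the first/last
#'   convolution (one of 32, 64, 128).
#' @param fc_size Width of the hidden dense layer (256 or 512).
#' @param n_classes Number of output classes (default 10: nine insect classes
#'   plus background).
#' @param input_size Input raster side in pixels; must be divisible by 16
#'   (default 128).
#'
#' @return A list of class `arch_spec`.
#' @export
#' @examples
#' arch_spec()  # the chosen architecture {5, 3, 32, 64, 512}
arch_spec <- function(kernel_first = 5, kernel_last = 3,
                      depth_first = 32, depth_last = 64,
                      fc_size = 512, n_classes = 10, input_size = 128) {
  check_in <- function(x, set, what) {
    if (!(x %in% set)) {
      stop(sprintf("%s must be one of {%s}", what, paste(set, collapse = ", ")))
    }
  }
  check_in(kernel_first, c(1, 3, 5), "kernel_first")
  check_in(kernel_last, c(1, 3, 5), "kernel_last")
  check_in(depth_first, c(32, 64, 128), "depth_first")
  check_in(depth_last, c(32, 64, 128), "depth_last")
  check_in(fc_size, c(256, 512), "fc_size")
  stopifnot(n_classes >= 2, input_size %% 16 == 0)
  structure(
    list(
      kernel_first = as.integer(kernel_first),
      kernel_last = as.integer(kernel_last),
      depth_first = as.integer(depth_first),
      depth_last = as.integer(depth_last),
      fc_size = as.integer(fc_size),
      n_classes = as.integer(n_classes),
      input_size = as.integer(input_size),
      middle_depth = 64L,
      middle_kernel = 3L
    ),
    class = "arch_spec"
  )
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf(
    "<arch_spec {%d, %d, %d, %d, %d}> input %dx%dx3, %d classes, %s parameters\n",
    x$kernel_first, x$kernel_last, x$depth_first, x$depth_last, x$fc_size,
    x$input_size, x$input_size, x$n_classes,
    format(count_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

#' Exact learnable-parameter count of an architecture
#'
#' Closed-form accounting of all weights and biases: for each convolution
#' `k^2 * c_in * c_out + c_out`, for each dense layer `n_in * n_out + n_out`.
#' The flatten width is `(input_size / 16)^2 * depth_last` (8*8*depth_last
#' for 128-pixel inputs). The chosen default architecture has 2,197,578
#' parameters.
#'
#' @param spec An [arch_spec()].
#' @return Integer parameter count.
#' @export
#' @examples
#' count_parameters(arch_spec(5, 3, 32, 64, 512))
count_parameters <- function(spec) {
  s <- spec
  side <- s$input_size %/% 16L
  flat <- side * side * s$depth_last
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  dense <- function(nin, nout) nin * nout + nout
  conv(s$kernel_first, 3L, s$depth_first) +
    conv(s$middle_kernel, s$depth_first, s$middle_depth) +
    conv(s$middle_kernel, s$middle_depth, s$middle_depth) +
    conv(s$kernel_last, s$middle_depth, s$depth_last) +
    dense(flat, s$fc_size) +
    dense(s$fc_size, s$n_classes)
}

#' Enumerate an architecture/optimizer grid
#'
#' Cartesian product of the supplied hyperparameter option sets. The default
#' sets are the combinations observed in the architecture ranking (first
#' kernel 3 or 5, last kernel 1 or 3, first depth 32 or 64, last depth 32,
#' 64 or 128, dense width 256 or 512, optimizer Adam or SGD).
#'
#' @param kernel_first,kernel_last,depth_first,depth_last,fc_size Numeric
#'   option vectors.
#' @param optimizers Character vector of optimizer names.
#' @return A tibble with one row per combination, a `spec` list-column of
#'   [arch_spec()] objects, and a `parameters` column.
#' @export
#' @examples
#' nrow(enumerate_grid())
enumerate_grid <- function(kernel_first = c(3, 5), kernel_last = c(1, 3),
                           depth_first = c(32, 64),
                           depth_last = c(32, 64, 128),
                           fc_size = c(256, 512),
                           optimizers = c("adam", "sgd")) {
  stopifnot(
    length(kernel_first) > 0, length(kernel_last) > 0,
    length(depth_first) > 0, length(depth_last) > 0,
    length(fc_size) > 0, length(optimizers) > 0
  )
  grid <- tidyr::expand_grid(
    kernel_first = kernel_first, kernel_last = kernel_last,
    depth_first = depth_first, depth_last = depth_last,
    fc_size = fc_size, optimizer = optimizers
  )
  grid |>
    dplyr::mutate(
      spec = purrr::pmap(
        list(.data$kernel_first, .data$kernel_last, .data$depth_first,
             .data$depth_last, .data$fc_size),
        arch_spec
      ),
      parameters = purrr::map_int(.data$spec, count_parameters)
    )
}

#' Training configuration for the species classifier
#'
#' @param optimizer `"adam"` (default; converges fastest on this data scale)
#'   or `"sgd"` (momentum 0.9).
#' @param epochs Number of passes over the training split.
#' @param batch_size Minibatch size.
#' @param lr Learning rate.
#' @param dropout Dropout probability between the hidden dense layer and the
#'   output (default 0.3).
#' @param split Training fraction of the stratified train/validation split
#'   (default 0.8).
#' @param augmentation_factor Augmented copies per source crop used by
#'   dataset-building callers (default 32).
#' @param seed Integer seed controlling the split, shuffling, dropout and
#'   weight initialization.
#'
#' @return A list of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), epochs = 10,
                         batch_size = 32, lr = 1e-3, dropout = 0.3,
                         split = 0.8, augmentation_factor = 32, seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(
    epochs >= 1, batch_size >= 1, lr > 0, dropout >= 0, dropout < 1,
    split > 0, split < 1, augmentation_factor >= 1
  )
  structure(
    list(
      optimizer = optimizer, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), lr = lr, dropout = dropout,
      split = split, augmentation_factor = as.integer(augmentation_factor),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}
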