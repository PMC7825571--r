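#' Build an untrained classifier model
#'
#' Allocates He-initialized weights for the architecture. The weight layout
#' is one matrix per layer: convolution weights are `(k^2 * c_in) x c_out`,
#' dense weights `n_in x n_out`, plus one bias vector per layer, so the total
#' number of weight entries equals [count_parameters()] exactly.
#'
#' @param spec An [arch_spec()].
#' @param classes Character vector of class labels, length `spec$n_classes`.
#' @param seed Seed for the weight initialization.
#' @return An object of class `moth_cnn`.
#' @export
#' @examples
#' m <- build_model(arch_spec(), seed = 1)
build_model <- function(spec = arch_spec(), classes = moth_classes(), seed = 1) {
  stopifnot(inherits(spec, "arch_spec"))
  if (length(classes) != spec$n_classes) {
    stop("length(classes) must equal spec$n_classes")
  }
  he <- function(nin, nout, k2 = 1) {
    matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  s <- spec
  flat <- (s$input_size %/% 16L)^2 * s$depth_last
  weights <- withr::with_seed(seed, list(
    W1 = he(s$kernel_first^2 * 3, s$depth_first),
    b1 = numeric(s$depth_first),
    W2 = he(9 * s$depth_first, 64),
    b2 = numeric(64),
    W3 = he(9 * 64, 64),
    b3 = numeric(64),
    W4 = he(s$kernel_last^2 * 64, s$depth_last),
    b4 = numeric(s$depth_last),
    W5 = he(flat, s$fc_size),
    b5 = numeric(s$fc_size),
    W6 = he(s$fc_size, s$n_classes),
    b6 = numeric(s$n_classes)
  ))
  structure(
    list(spec = spec, classes = classes, weights = weights,
         trained = FALSE, history = NULL, validation = NULL),
    class = "moth_cnn"
  )
}

#' @export
print.moth_cnn <- function(x, ...) {
  cat(sprintf(
    "<moth_cnn> %s, %s parameters, %s\n",
    paste0("{", paste(unlist(x$spec[1:5]), collapse = ", "), "}"),
    format(count_parameters(x$spec), big.mark = ","),
    if (x$trained) {
      sprintf("trained (validation macro-F1 %.3f)", x$validation$macro_f1)
    } else "untrained"
  ))
  invisible(x)
}

# Total number of weight entries actually allocated; must agree with the
# closed-form count_parameters() for every spec (tested over the whole grid).
model_parameter_total <- function(model) {
  sum(vapply(model$weights, length, numeric(1)))
}

#' Train the species classifier
#'
#' Splits the labeled crops into stratified training/validation parts,
#' minimizes the softmax cross-entropy with the configured optimizer, and
#' attaches a validation report (per-class precision/recall/F1, macro F1,
#' confusion matrix) to the returned model. Training is seeded and can be
#' resumed by calling `train_cnn()` again on the returned model.
#'
#' @param model A `moth_cnn` from [build_model()].
#' @param crops A crop tibble from [crop_dataset()] / [augment()]: columns
#'   `class` and `image`.
#' @param config A [train_config()].
#' @param verbose Print per-epoch loss/accuracy.
#' @return The trained `moth_cnn` with `history` and `validation` filled in.
#' @export
train_cnn <- function(model, crops, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "moth_cnn"))
  crops <- validate_crops(crops, model$spec$input_size)
  present <- unique(as.character(crops$class))
  if (length(present) < 2) {
    stop("training requires at least two classes present in the data")
  }
  unknown <- setdiff(present, model$classes)
  if (length(unknown)) {
    stop("crop classes not known to the model: ", paste(unknown, collapse = ", "))
  }
  idx_split <- withr::with_seed(config$seed, stratified_split(
    as.character(crops$class), config$split
  ))
  train_idx <- idx_split$train
  val_idx <- idx_split$val
  if (!all(present %in% as.character(crops$class[train_idx])) ||
      !all(present %in% as.character(crops$class[val_idx]))) {
    stop("each class must appear in both the training and validation split")
  }
  lab <- match(as.character(crops$class), model$classes) - 1L
  fit <- cnn_train_cpp(
    crops$image[train_idx], lab[train_idx], model$weights,
    model$spec, config$epochs, config$batch_size, config$optimizer,
    config$lr, config$dropout, config$seed, verbose
  )
  model$weights <- fit$weights
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(
    model$history,
    tibble::tibble(
      epoch = seq_along(fit$loss) + (nrow(model$history %||% tibble::tibble())),
      loss = as.numeric(fit$loss),
      accuracy = as.numeric(fit$accuracy)
    )
  )
  # validation report
  probs <- cnn_predict_cpp(crops$image[val_idx], model$weights, model$spec)
  pred <- model$classes[max.col(probs, ties.method = "first")]
  truth <- as.character(crops$class[val_idx])
  model$validation <- validation_report(truth, pred, model$classes)
  model$validation$n_train <- length(train_idx)
  model$validation$n_val <- length(val_idx)
  model
}

# Per-class TP/FP/FN, precision/recall/F1 and macro-F1 from label vectors.
validation_report <- function(truth, pred, classes) {
  confusion <- table(
    truth = factor(truth, levels = classes),
    predicted = factor(pred, levels = classes)
  )
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  metrics <- purrr::pmap(
    list(tp, fp, fn, classes),
    function(tp, fp, fn, cl) {
      if (tp + fp + fn == 0) {
        tibble::tibble(class = cl, TP = 0, FP = 0, FN = 0,
                       precision = NA_real_, recall = NA_real_, f1 = NA_real_)
      } else {
        dplyr::mutate(class_metrics(tp, fp, fn), class = cl, .before = 1)
      }
    }
  ) |> dplyr::bind_rows()
  list(
    metrics = metrics,
    confusion = confusion,
    macro_f1 = mean(metrics$f1, na.rm = TRUE),
    accuracy = sum(tp) / length(truth)
  )
}

stratified_split <- function(labels, split) {
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, floor(length(idx) * split))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train), val = sort(setdiff(seq_along(labels), train)))
}

#' Predict species for crops
#'
#' @param object A trained (or untrained) `moth_cnn`.
#' @param newdata A crop tibble, a list of crop rasters, or a single raster
#'   (raw or numeric `size x size x 3` array).
#' @param type `"label"` for a tibble of argmax labels and confidences,
#'   `"prob"` for the full softmax probability matrix.
#' @param ... Unused.
#' @return A tibble with `label` and `confidence`, or a probability matrix
#'   with one row per crop (rows sum to 1).
#' @export
predict.moth_cnn <- function(object, newdata, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  images <- coerce_images(newdata, object$spec$input_size)
  probs <- cnn_predict_cpp(images, object$weights, object$spec)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  k <- max.col(probs, ties.method = "first")
  tibble::tibble(
    label = object$classes[k],
    confidence = probs[cbind(seq_len(nrow(probs)), k)]
  )
}

coerce_images <- function(newdata, size) {
  single <- function(x) {
    if (is.raw(x)) {
      if (length(x) != size * size * 3) {
        stop(sprintf("crop must be %dx%dx3", size, size))
      }
      return(x)
    }
    d <- dim(x)
    if (is.null(d) || length(d) != 3 || d[1] != size || d[2] != size || d[3] != 3) {
      stop(sprintf("crop must be %dx%dx3", size, size))
    }
    as_crop_raw(x)
  }
  if (is.data.frame(newdata)) {
    lapply(newdata$image, single)
  } else if (is.list(newdata) && !is.array(newdata)) {
    lapply(newdata, single)
  } else {
    list(single(newdata))
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the validation report of a trained classifier
#'
#' @param x A trained `moth_cnn`.
#' @param ... Unused.
#' @return One row per class with `TP`, `FP`, `FN`, `precision`, `recall`,
#'   `f1` on the validation split.
#' @export
tidy.moth_cnn <- function(x, ...) {
  if (!x$trained) stop("model has not been trained")
  x$validation$metrics
}

#' One-row summary of a trained classifier
#'
#' @param x A trained `moth_cnn`.
#' @param ... Unused.
#' @return A tibble with `parameters`, `macro_f1`, `accuracy`, `n_train`,
#'   `n_val`, `epochs`.
#' @export
glance.moth_cnn <- function(x, ...) {
  if (!x$trained) stop("model has not been trained")
  tibble::tibble(
    parameters = count_parameters(x$spec),
    macro_f1 = x$validation$macro_f1,
    accuracy = x$validation$accuracy,
    n_train = x$validation$n_train,
    n_val = x$validation$n_val,
    epochs = nrow(x$history)
  )
}

#' Persist / load a classifier model
#'
#' @param model A `moth_cnn`.
#' @param path File path for the single weights file.
#' @return `write_model()` returns `path` invisibly; `read_model()` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "moth_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "moth_cnn")) stop("not a moth_cnn model file: ", path)
  model
}
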