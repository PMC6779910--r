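# Probabilistic linear classification of embedding vectors: multinomial
# logistic regression with an L2 penalty, the classifier used throughout
# the supervised workflow.

#' Train a logistic-regression classifier on embeddings
#'
#' Multinomial (softmax) logistic regression with an L2 penalty of strength
#' `1/C` on the weights (intercepts unpenalized), fitted with
#' [glmnet::glmnet()] (ridge path, `standardize = FALSE`, penalty
#' `lambda = 1/(nC)` so the objective matches the familiar
#' `sum(log-loss) + ||W||^2 / (2C)` convention). The defaults `C = 1`,
#' `max_iter = 1000` mirror common library defaults and are recorded in the
#' fitted model for auditability. The fit is deterministic given inputs.
#'
#' @param E An `embedding_matrix` whose table is fully labeled with at
#'   least two classes.
#' @param C Inverse regularization strength (> 0), default 1.
#' @param max_iter Optimizer iteration budget, default 1000.
#' @param seed Integer seed (the solver is deterministic; kept for a uniform
#'   interface and recorded in the model).
#' @return A `logreg_model`: `classes` (ordered label list), `weights`
#'   (`#classes x d`), `intercepts`, `backend_name` and `hyperparameters`.
#' @export
train_logreg <- function(E, C = 1, max_iter = 1000L, seed = 0L) {
  if (!inherits(E, "embedding_matrix")) abort_input("`E` must be an embedding_matrix")
  if (!is.numeric(C) || length(C) != 1L || C <= 0) abort_input("`C` must be > 0")
  labels <- E$table$label
  if (anyNA(labels)) {
    abort_input(sprintf("%d unlabeled rows; training needs a fully labeled table",
                        sum(is.na(labels))))
  }
  classes <- class_values(E$table)
  classes <- classes[classes %in% labels] # classes actually present
  if (length(classes) < 2L) {
    abort_input("training needs at least 2 classes with examples")
  }
  y <- factor(labels, levels = classes)
  x <- E$values
  d <- ncol(x)
  if (d < 2L) x <- cbind(x, pad = 0) # glmnet needs >= 2 columns
  if (min(table(y)) < 2L) {
    # replicate the data; with the penalty scaled per observation the
    # optimum is unchanged, and the solver's per-class minimum is met
    x <- x[rep(seq_len(nrow(x)), 2L), , drop = FALSE]
    y <- y[rep(seq_along(y), 2L)]
  }
  n <- nrow(x)
  lambda <- 1 / (n * C)
  if (all(apply(x, 2L, function(col) max(col) - min(col)) == 0)) {
    # no informative features: intercept-only maximum-likelihood model
    prop <- as.numeric(table(y)) / length(y)
    return(structure(list(classes = classes,
                          weights = matrix(0, length(classes), d),
                          intercepts = log(prop) - mean(log(prop)),
                          backend_name = E$backend$name,
                          hyperparameters = list(C = C, max_iter = max_iter,
                                                 seed = seed, penalty = "l2",
                                                 solver = "intercept-only",
                                                 lambda = lambda)),
                     class = "logreg_model"))
  }
  set.seed(seed)
  fit <- withCallingHandlers(
    glmnet::glmnet(
      x, y, family = "multinomial", alpha = 0,
      lambda = lambda * c(1000, 100, 10, 1), standardize = FALSE,
      thresh = 1e-12, maxit = max(1e5, max_iter * 100)
    ),
    warning = function(w) {
      # small folds routinely trip glmnet's class-size caution; the fit
      # itself is well defined, so keep the log clean
      if (grepl("fewer than 8|dangerous ground", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- coef(fit, s = lambda)
  weights <- do.call(rbind, lapply(co, function(m) as.numeric(m)[-1L][seq_len(d)]))
  intercepts <- vapply(co, function(m) as.numeric(m)[1L], numeric(1))
  structure(list(classes = classes, weights = unname(weights),
                 intercepts = unname(intercepts),
                 backend_name = E$backend$name,
                 hyperparameters = list(C = C, max_iter = max_iter, seed = seed,
                                        penalty = "l2", solver = "glmnet-ridge",
                                        lambda = lambda)),
            class = "logreg_model")
}

#' @method print logreg_model
#' @export
print.logreg_model <- function(x, ...) {
  cat(sprintf("<logreg_model> %d classes (%s), %d features, C = %g (backend: %s)\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              ncol(x$weights), x$hyperparameters$C, x$backend_name))
  invisible(x)
}

#' @method coef logreg_model
#' @export
coef.logreg_model <- function(object, ...) {
  out <- cbind(intercept = object$intercepts, object$weights)
  rownames(out) <- object$classes
  out
}

model_scores <- function(model, E) {
  X <- if (inherits(E, "embedding_matrix")) E$values else as.matrix(E)
  if (ncol(X) != ncol(model$weights)) {
    abort_input(sprintf("feature dimension mismatch: model expects %d, got %d",
                        ncol(model$weights), ncol(X)))
  }
  sweep(X %*% t(model$weights), 2L, model$intercepts, `+`)
}

#' Class probabilities from a fitted model
#'
#' Softmax of the affine scores; each row sums to one.
#'
#' @param model A `logreg_model`.
#' @param E An `embedding_matrix` or numeric matrix with matching feature
#'   dimension.
#' @return `n x #classes` probability matrix, columns named by class.
#' @export
predict_proba <- function(model, E) {
  S <- model_scores(model, E)
  S <- S - apply(S, 1L, max) # stabilized softmax
  P <- exp(S)
  P <- P / rowSums(P)
  dimnames(P) <- list(NULL, model$classes)
  P
}

#' Class predictions from a fitted model
#'
#' Argmax of [predict_proba()]; exact probability ties are broken toward
#' the earlier class in `model$classes`.
#'
#' @inheritParams predict_proba
#' @return Character vector of predicted labels.
#' @export
predict_class <- function(model, E) {
  P <- predict_proba(model, E)
  model$classes[max.col(P, ties.method = "first")]
}

#' @method predict logreg_model
#' @export
predict.logreg_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "class") predict_class(object, newdata) else predict_proba(object, newdata)
}

#' Save a fitted model as JSON
#'
#' Classes, weights, intercepts, backend provenance and hyperparameters,
#' written at full precision so a reloaded model reproduces predictions
#' exactly.
#'
#' @param model A `logreg_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_model_json <- function(model, path) {
  obj <- list(classes = model$classes, weights = model$weights,
              intercepts = model$intercepts, backend_name = model$backend_name,
              hyperparameters = model$hyperparameters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path JSON path written by [save_model_json()].
#' @return A `logreg_model`.
#' @export
load_model_json <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such model file: '%s'", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(classes = obj$classes,
                 weights = matrix(as.numeric(obj$weights), nrow = length(obj$classes)),
                 intercepts = as.numeric(obj$intercepts),
                 backend_name = obj$backend_name,
                 hyperparameters = obj$hyperparameters),
            class = "logreg_model")
}
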