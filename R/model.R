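# Undersampling ensemble of gradient-boosted tree classifiers.
#
# Training draws k class-balanced datasets (all SHBs plus an equal-size
# random subset of NHBs, sampled without replacement within each dataset),
# selects the tree interaction depth for each by 10-fold cross-validation
# over candidates 1..12, retrains each member on its full balanced dataset,
# and averages the members' SHB probabilities at prediction time. The
# boosting objective is the exponential (AdaBoost) loss, implemented as a
# custom objective on top of xgboost; member probabilities use the matching
# half-logit link p = 1 / (1 + exp(-2 f)). A binomial-deviance objective is
# available behind the `loss` config flag.

DEFAULT_THRESHOLD <- 0.870

#' Training configuration
#'
#' Defaults follow the reference protocol: 10 ensemble members, 5000 trees
#' per member, shrinkage 0.01, exponential loss, interaction depth chosen
#' from 1..12 by 10-fold cross-validation.
#'
#' @param n_members number of balanced datasets / boosting members.
#' @param n_trees boosting iterations per member.
#' @param shrinkage learning rate in (0, 1].
#' @param loss `"exponential"` (AdaBoost objective) or `"deviance"`
#'   (binomial log-loss).
#' @param depth_candidates candidate interaction depths.
#' @param cv_folds folds for depth selection.
#' @param undersample draw a balanced NHB subsample per member (`TRUE`,
#'   the default protocol); `FALSE` trains every member on the full
#'   training set (the more conservative no-undersampling variant).
#' @param rng_seed integer seed controlling subsampling, fold assignment
#'   and tree fitting.
#' @return `shb_config` list.
#' @export
shb_config <- function(n_members = 10, n_trees = 5000, shrinkage = 0.01,
                       loss = c("exponential", "deviance"),
                       depth_candidates = 1:12, cv_folds = 10,
                       undersample = TRUE, rng_seed = 1) {
  loss <- match.arg(loss)
  stopifnot(n_members >= 1, n_trees >= 1,
            shrinkage > 0, shrinkage <= 1,
            length(depth_candidates) >= 1, all(depth_candidates >= 1),
            cv_folds >= 2)
  structure(list(n_members = as.integer(n_members),
                 n_trees = as.integer(n_trees),
                 shrinkage = shrinkage, loss = loss,
                 depth_candidates = as.integer(sort(unique(depth_candidates))),
                 cv_folds = as.integer(cv_folds),
                 undersample = isTRUE(undersample),
                 rng_seed = as.integer(rng_seed)),
            class = "shb_config")
}

label_to_binary <- function(label) {
  lab <- toupper(as.character(label))
  if (!all(lab %in% c("SHB", "NHB")))
    stop("labels must be SHB or NHB")
  as.integer(lab == "SHB")
}

#' Create class-balanced training datasets by undersampling
#'
#' Each dataset contains every SHB record plus an equal number of NHB
#' records drawn without replacement (within the dataset; overlap across
#' datasets is allowed). Sub-seeds for the k draws are derived from `seed`.
#'
#' @param train labeled feature table (must contain both classes, with at
#'   least as many NHBs as SHBs).
#' @param k number of datasets.
#' @param seed integer seed.
#' @return list of k data.frames.
#' @export
make_balanced_datasets <- function(train, k, seed = 1) {
  y <- label_to_binary(train$label)
  n_shb <- sum(y == 1); n_nhb <- sum(y == 0)
  if (n_shb == 0 || n_nhb == 0)
    stop("training data must contain both SHB and NHB records")
  if (n_nhb < n_shb)
    stop("undersampling expects at least as many NHBs as SHBs")
  shb_idx <- which(y == 1); nhb_idx <- which(y == 0)
  lapply(seq_len(k), function(m) {
    set.seed((as.integer(seed) + 7919L * m) %% .Machine$integer.max)
    sel <- sample(nhb_idx, n_shb, replace = FALSE)
    out <- train[c(shb_idx, sel), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# ---- categorical encoding --------------------------------------------------

CAT_FEATURES <- c("aa_residue", "aa_heteroatom", "lig_functional_group",
                  "seq_m3", "seq_m2", "seq_m1", "seq_p1", "seq_p2", "seq_p3")
NUM_FEATURES <- c("aa_charge", "lig_charge", "lig_pKa", "lig_pKb", "lig_logP")

# Closed vocabularies frozen with the model; UNK absorbs unseen levels.
build_vocab <- function(train) {
  v <- list()
  seq_levels <- sort(unique(c(STANDARD_AA, "XTR", "UNK")))
  for (f in CAT_FEATURES) {
    v[[f]] <- switch(f,
      aa_residue = c(sort(STANDARD_AA), "UNK"),
      aa_heteroatom = sort(unique(c(unlist(AA_HETEROATOMS),
                                    unique(train[[f]]), "UNK"))),
      lig_functional_group = c(FG_ORDERED, "OTHER", "UNK"),
      seq_levels)
  }
  v
}

# Indicator (one-hot) expansion with frozen levels; numeric features pass
# through, missing values stay NA (handled natively by the trees).
encode_features <- function(tb, vocab, warn_unknown = TRUE) {
  miss <- setdiff(c(CAT_FEATURES, NUM_FEATURES), names(tb))
  if (length(miss) > 0)
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(tb)
  cols <- list()
  for (f in NUM_FEATURES) cols[[f]] <- as.numeric(tb[[f]])
  for (f in CAT_FEATURES) {
    lv <- vocab[[f]]
    x <- as.character(tb[[f]])
    unknown <- !(x %in% lv) & !is.na(x)
    if (any(unknown)) {
      if (warn_unknown)
        warning("unknown level(s) in ", f, ": ",
                paste(unique(x[unknown]), collapse = ", "),
                "; mapped to UNK")
      x[unknown] <- "UNK"
    }
    for (l in lv) cols[[paste0(f, "=", l)]] <- as.numeric(x == l)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

# xgboost exponential-loss objective on the margin f: L = exp(-(2y-1) f).
exp_objective <- function(preds, dtrain) {
  y <- xgboost::getinfo(dtrain, "label")
  s <- 2 * y - 1
  e <- exp(-s * preds)
  list(grad = -s * e, hess = e)
}

member_params <- function(config, depth) {
  p <- list(max_depth = as.integer(depth), eta = config$shrinkage,
            nthread = 1)
  if (config$loss == "deviance") p$objective <- "binary:logistic"
  else p$base_score <- 0  # raw-margin start for the custom objective
  p
}

fit_member <- function(x, y, config, depth, seed) {
  set.seed(seed %% .Machine$integer.max)
  dtr <- xgboost::xgb.DMatrix(x, label = y)
  if (config$loss == "exponential") {
    bst <- xgboost::xgb.train(params = member_params(config, depth),
                              data = dtr, nrounds = config$n_trees,
                              obj = exp_objective, verbose = 0)
  } else {
    bst <- xgboost::xgb.train(params = member_params(config, depth),
                              data = dtr, nrounds = config$n_trees,
                              verbose = 0)
  }
  bst
}

member_proba <- function(bst, x, loss) {
  f <- predict(bst, x, outputmargin = TRUE)
  if (loss == "exponential") 1 / (1 + exp(-2 * f)) else 1 / (1 + exp(-f))
}

member_loss <- function(p, y, loss) {
  eps <- 1e-12
  p <- pmin(1 - eps, pmax(eps, p))
  if (loss == "exponential") {
    f <- 0.5 * log(p / (1 - p))
    mean(exp(-(2 * y - 1) * f))
  } else {
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

#' Select the tree interaction depth by cross-validation
#'
#' Splits the balanced dataset into `cv_folds` equal folds, fits every
#' candidate depth on each training split, scores the held-out fold with
#' the configured loss, and returns the depth with the lowest mean
#' validation loss (ties go to the smallest depth).
#'
#' @param x encoded feature matrix.
#' @param y binary labels (1 = SHB).
#' @param config `shb_config`.
#' @param seed seed for the fold assignment and fits.
#' @return selected depth (integer).
#' @export
select_interaction_depth <- function(x, y, config, seed = 1) {
  cands <- config$depth_candidates
  if (length(cands) == 1) return(cands)
  n <- nrow(x)
  if (n < config$cv_folds)
    stop("dataset smaller than the number of CV folds")
  set.seed(seed %% .Machine$integer.max)
  fold <- sample(rep_len(seq_len(config$cv_folds), n))
  mean_loss <- vapply(cands, function(d) {
    losses <- vapply(seq_len(config$cv_folds), function(k) {
      tr <- fold != k
      bst <- fit_member(x[tr, , drop = FALSE], y[tr], config, d,
                        seed + 131L * k + d)
      p <- member_proba(bst, x[!tr, , drop = FALSE], config$loss)
      member_loss(p, y[!tr], config$loss)
    }, numeric(1))
    mean(losses)
  }, numeric(1))
  cands[which.min(mean_loss)]  # which.min takes the first (smallest) on ties
}

#' Train the undersampling boosting ensemble
#'
#' @param train labeled feature table.
#' @param config from [shb_config()].
#' @return object of class `shb_ensemble`: fitted members (raw tree dumps),
#'   per-member selected depths, frozen categorical vocabularies, training
#'   class counts and the default classification threshold 0.870.
#' @export
train_ensemble <- function(train, config = shb_config()) {
  y_all <- label_to_binary(train$label)
  if (config$undersample) {
    datasets <- make_balanced_datasets(train, config$n_members,
                                       config$rng_seed)
  } else {
    if (length(unique(y_all)) < 2)
      stop("training data must contain both SHB and NHB records")
    datasets <- rep(list(train), config$n_members)
  }
  vocab <- build_vocab(train)
  members <- vector("list", config$n_members)
  depths <- integer(config$n_members)
  for (m in seq_len(config$n_members)) {
    ds <- datasets[[m]]
    x <- encode_features(ds, vocab, warn_unknown = FALSE)
    y <- label_to_binary(ds$label)
    seed_m <- config$rng_seed + 7919L * m
    depth <- tryCatch(
      select_interaction_depth(x, y, config, seed_m),
      error = function(e) stop("member ", m, ": ", conditionMessage(e)))
    bst <- tryCatch(
      fit_member(x, y, config, depth, seed_m + 1L),
      error = function(e) stop("member ", m, ": ", conditionMessage(e)))
    members[[m]] <- xgboost::xgb.save.raw(bst)
    depths[m] <- depth
  }
  structure(list(members = members, depths = depths, vocab = vocab,
                 config = config, threshold = DEFAULT_THRESHOLD,
                 class_counts = c(SHB = sum(y_all == 1),
                                  NHB = sum(y_all == 0)),
                 feature_names = colnames(encode_features(head(train, 1),
                                                          vocab,
                                                          warn_unknown = FALSE)),
                 version = "1"),
            class = "shb_ensemble")
}

#' @export
print.shb_ensemble <- function(x, ...) {
  cat(sprintf(paste0("shb_ensemble: %d member(s), %d trees each, %s loss\n",
                     "selected depths: %s\ntraining classes: %d SHB / %d NHB\n",
                     "classification threshold: %.3f\n"),
              length(x$members), x$config$n_trees, x$config$loss,
              paste(x$depths, collapse = " "), x$class_counts["SHB"],
              x$class_counts["NHB"], x$threshold))
  invisible(x)
}

ensemble_boosters <- function(m) {
  lapply(m$members, xgboost::xgb.load.raw)
}

#' Predict SHB probabilities
#'
#' Averages the SHB probability of every ensemble member. Unknown
#' categorical levels are mapped to UNK with a warning.
#'
#' @param m `shb_ensemble`.
#' @param newdata feature table.
#' @param per_member return the member-wise probability matrix as the
#'   `"members"` attribute.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(m, newdata, per_member = FALSE) {
  x <- encode_features(newdata, m$vocab)
  pm <- vapply(ensemble_boosters(m), function(b)
    member_proba(b, x, m$config$loss), numeric(nrow(x)))
  pm <- matrix(pm, nrow = nrow(x))
  p <- rowMeans(pm)
  if (per_member) attr(p, "members") <- pm
  p
}

#' Classify probabilities into SHB / NHB
#'
#' A bond is an SHB when its probability is greater than or equal to the
#' threshold (default 0.870).
#'
#' @param p probabilities in [0, 1].
#' @param threshold classification threshold in [0, 1].
#' @return character vector of `"SHB"` / `"NHB"`.
#' @export
classify <- function(p, threshold = DEFAULT_THRESHOLD) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  ifelse(p >= threshold, "SHB", "NHB")
}

# ---- serialization ---------------------------------------------------------

vocab_hash <- function(vocab, feature_names) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(unlist(vocab), feature_names), tmp)
  unname(tools::md5sum(tmp))
}

#' Save / load a fitted ensemble
#'
#' The archive stores per-member raw tree dumps, the frozen categorical
#' vocabularies, the training configuration and a schema hash which is
#' validated on load.
#'
#' @param m `shb_ensemble`.
#' @param path archive path.
#' @export
save_model <- function(m, path) {
  m$schema_hash <- vocab_hash(m$vocab, m$feature_names)
  saveRDS(m, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "shb_ensemble")) stop("not an ensemble archive: ", path)
  if (!identical(m$schema_hash, vocab_hash(m$vocab, m$feature_names)))
    stop("model archive failed schema validation")
  m
}
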