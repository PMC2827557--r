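# Shared fixtures and independent brute-force oracles.

# A tiny two-class expression set with one perfectly separating gene and
# `n_noise` pure-noise genes.
separable_set <- function(n_per_class = 20, n_noise = 3, seed = 100) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n_noise * n), n_noise, n,
              dimnames = list(paste0("noise", seq_len(n_noise)),
                              paste0("s", seq_len(n))))
  sep <- c(runif(n_per_class, 0, 1), runif(n_per_class, 5, 6))
  x <- rbind(sep = sep, x)
  list(x = x,
       labels = rep(c("non_inflammatory", "inflammatory"),
                    each = n_per_class))
}

# Brute-force re-evaluation of one stored tree for a single sample
# (independent of predict.dc_forest, which goes through predict.randomForest).
eval_tree_oracle <- function(tree, xrow) {
  node <- 1L
  while (tree[node, "status"] != -1L) {
    node <- if (xrow[tree[node, "split var"]] <= tree[node, "split point"])
      tree[node, "left daughter"] else tree[node, "right daughter"]
  }
  tree[node, "prediction"]  # class index: 1 non_inflammatory, 2 inflammatory
}

# Per-tree class-index predictions for all rows of newx (samples x genes).
forest_votes_oracle <- function(model, newx) {
  vapply(seq_len(model$rf$ntree), function(k) {
    tree <- randomForest::getTree(model$rf, k, labelVar = FALSE)
    apply(newx, 1L, eval_tree_oracle, tree = tree)
  }, numeric(nrow(newx)))
}

# Independent OOB recomputation from stored bootstrap membership.
oob_error_oracle <- function(model) {
  votes <- forest_votes_oracle(model, model$x_samples)
  oob <- model$rf$inbag == 0L
  inf <- rowSums((votes == 2L) & oob)
  n_oob <- rowSums(oob)
  pred <- ifelse(inf > n_oob / 2, "inflammatory", "non_inflammatory")
  use <- n_oob > 0L
  mean(pred[use] != as.character(model$y[use]))
}

# Enumeration oracle for the direction-aware 0/1 scoring rule, transcribing
# the rule case by case.
score_oracle <- function(value, threshold, direction, claimed) {
  if (direction == "up" && claimed == "inflammatory") return(as.integer(value > threshold))
  if (direction == "up" && claimed == "non_inflammatory") return(as.integer(value < threshold))
  if (direction == "down" && claimed == "inflammatory") return(as.integer(value < threshold))
  if (direction == "down" && claimed == "non_inflammatory") return(as.integer(value > threshold))
  stop("bad case")
}

two_group_sizes <- function(n_inf = 30L, n_ninf = 30L) {
  data.frame(stimulus = c("untreated", "lps"), n = c(n_ninf, n_inf),
             class = c("non_inflammatory", "inflammatory"),
             stringsAsFactors = FALSE)
}
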