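# Shared fixtures, built lazily and cached for the whole test run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_params <- function(seed = 1L, ...) {
  scene_params(width = 96, height = 96, seed = seed, ...)
}

# A small trained nuclei model + its training scenes, reused by several files.
small_model_fixture <- function() {
  fixture("small_model", function() {
    scenes <- lapply(1:3, function(i) generate_scene(small_params(seed = i)))
    cfg <- train_config(patch_size = 16L, epochs = 3L, patches_per_scene = 120L,
                        seed = 1L)
    patches <- combine_patch_sets(lapply(scenes, extract_patches, config = cfg))
    model <- train_classifier(patches, cfg)
    list(model = model, config = cfg, scenes = scenes,
         test_scene = generate_scene(small_params(seed = 99L)))
  })
}

# A flat uint8 RGB test image.
flat_image <- function(value = 128L, h = 64L, w = 64L) {
  array(as.integer(value), dim = c(h, w, 3L))
}

# Brute-force one-to-one assignment oracle: maximise matched pairs within
# `radius`, break ties by minimum total distance. Exponential search over
# all pred -> gt injections; fine for <= 7 points per side.
brute_force_match <- function(pred, gt, radius) {
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0L || ng == 0L) return(list(tp = 0L, dist = 0))
  d <- sqrt(outer(pred$row, gt$row, "-")^2 + outer(pred$col, gt$col, "-")^2)
  best <- list(tp = 0L, dist = 0)
  recurse <- function(i, used, tp, dist) {
    if (i > np) {
      if (tp > best$tp || (tp == best$tp && dist < best$dist)) {
        best <<- list(tp = tp, dist = dist)
      }
      return(invisible())
    }
    # upper bound pruning not needed at this size
    recurse(i + 1L, used, tp, dist)                 # leave pred i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && d[i, j] <= radius) {
        used[j] <- TRUE
        recurse(i + 1L, used, tp + 1L, dist + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(ng), 0L, 0)
  best
}

# Exhaustive pair-counting AUC oracle.
pairwise_auc <- function(scores, labels) {
  pos <- which(labels > 0); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
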