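SEASONAL_SPECIES <- c(
  "Melia azedarach", "Morus alba", "Phoenix dactylifera",
  "Eriobotrya japonica", "Ceratonia siliqua"
)
UNPREDICTABLE_SPECIES <- c("Ficus religiosa", "Ficus microcarpa")
FOCAL_SPECIES <- "Ficus sycomorus"

#' Generate a synthetic fruit-tree landscape
#'
#' Places `n_trees` trees uniformly over a square landscape. Each tree is
#' independently assigned to a temporally unpredictable (Ficus-like) species
#' with probability `frac_unpredictable` (default 0.07, the approximate
#' fraction of unpredictable species in the study landscape); all others are
#' seasonal. Exactly `n_focal` trees are marked focal: these model the only
#' individuals of the manipulation-target fig species in the landscape and
#' are always unpredictable.
#'
#' @param config a [sim_config()].
#' @return a tibble with columns `tree_id`, `x`, `y`, `species`,
#'   `predictability` (`"seasonal"` or `"unpredictable"`), `is_focal`.
#' @export
generate_landscape <- function(config = sim_config()) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_trees
  if (n == 0) {
    return(tibble(
      tree_id = integer(), x = numeric(), y = numeric(),
      species = character(), predictability = character(),
      is_focal = logical()
    ))
  }
  unpred <- runif(n) < config$frac_unpredictable
  species <- ifelse(
    unpred,
    sample(UNPREDICTABLE_SPECIES, n, replace = TRUE),
    sample(SEASONAL_SPECIES, n, replace = TRUE)
  )
  is_focal <- rep(FALSE, n)
  if (config$n_focal > 0) {
    focal_idx <- sample.int(n, config$n_focal)
    is_focal[focal_idx] <- TRUE
    unpred[focal_idx] <- TRUE
    species[focal_idx] <- FOCAL_SPECIES
  }
  tibble(
    tree_id = seq_len(n),
    x = runif(n, 0, config$extent),
    y = runif(n, 0, config$extent),
    species = species,
    predictability = ifelse(unpred, "unpredictable", "seasonal"),
    is_focal = is_focal
  )
}

roost_table <- function(config) {
  k <- max(1L, as.integer(config$n_roosts))
  if (k == 1L) {
    return(tibble(roost = "R1", x = config$roost_xy[1], y = config$roost_xy[2]))
  }
  tibble(
    roost = paste0("R", seq_len(k)),
    x = config$roost_xy[1],
    y = seq(config$extent * 0.25, config$extent * 0.75, length.out = k)
  )
}
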