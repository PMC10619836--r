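#' Heritable trait machinery
#'
#' Agents carry six heritable traits. Each trait is stored as an ordered
#' expression class (`extra_small < small < medium < big < extra_big`) plus a
#' continuous, dimensionless advantage factor drawn inside that class's
#' bounds. The factor, not the class label, is what the behavioural rules
#' consume, after trait-specific scaling (see [ability_value()]).
#'
#' @name genetics
NULL

#' Trait and expression-class vocabularies
#'
#' @return `trait_names()` returns the six trait identifiers in canonical
#'   order; `expression_levels()` the five ordered expression-class labels.
#' @export
trait_names <- function() {
  c("detection_range", "tailfat", "dominance",
    "bite_force", "hearing", "binocular_vision")
}

#' @rdname trait_names
#' @export
expression_levels <- function() {
  c("extra_small", "small", "medium", "big", "extra_big")
}

#' Advantage-factor bounds per expression class
#'
#' Classes partition the factor range 0.3--1.7. Intervals are half-open
#' `[lo, hi)` except the topmost, which is closed, so every factor maps to
#' exactly one class.
#'
#' @return A 5 x 2 numeric matrix (`lo`, `hi`) with one row per expression
#'   class, in class order.
#' @export
factor_bounds <- function() {
  m <- cbind(lo = c(0.30, 0.65, 0.90, 1.10, 1.35),
             hi = c(0.65, 0.90, 1.10, 1.35, 1.70))
  rownames(m) <- expression_levels()
  m
}

#' Map an advantage factor to its expression class
#'
#' @param factor numeric vector of advantage factors in `[0.3, 1.7]`.
#' @return character vector of class labels.
#' @export
expression_of_factor <- function(factor) {
  stopifnot(is.numeric(factor), all(factor >= 0.3), all(factor <= 1.7))
  b <- factor_bounds()
  idx <- findInterval(factor, c(b[, "lo"], 1.7), rightmost.closed = TRUE)
  expression_levels()[idx]
}

#' Trait scaling table
#'
#' Trait scalings are data, not code: abilities are affine transforms
#' `ability = scale * factor + offset` of the advantage factor, so
#' alternative scalings can be supplied through the configuration.
#' Defaults: carcass detection range 5 km x factor; fat-storage (daily
#' intake cap) 38 kg x factor; prey detection (binocular vision) 0.5 km x
#' factor; kill probability 0.1 x factor; dominance and hearing are the
#' centred factor (factor - 1).
#'
#' @return data.frame with columns `trait`, `scale`, `offset`, `unit`.
#' @export
default_trait_table <- function() {
  data.frame(
    trait  = trait_names(),
    scale  = c(5, 38, 1, 0.1, 1, 0.5),
    offset = c(0, 0, -1, 0, -1, 0),
    unit   = c("km", "kg/day", "score", "probability", "score", "km"),
    stringsAsFactors = FALSE
  )
}

#' Scale an advantage factor into a usable ability
#'
#' @param trait character, one of [trait_names()] (recycled against
#'   `factor`).
#' @param factor numeric advantage factor(s).
#' @param table trait scaling table, as [default_trait_table()].
#' @return numeric ability value(s) in the trait's natural unit.
#' @examples
#' ability_value("tailfat", 1.7)          # 64.6 kg/day
#' ability_value("dominance", 0.77)       # -0.23
#' ability_value("bite_force", 1.0)       # 0.10 kill probability
#' @export
ability_value <- function(trait, factor, table = default_trait_table()) {
  i <- match(trait, table$trait)
  if (anyNA(i)) {
    stop("unknown trait: ", paste(unique(trait[is.na(i)]), collapse = ", "))
  }
  table$scale[i] * factor + table$offset[i]
}

#' Expression-class inheritance kernel
#'
#' Offspring keep the parental class with probability 0.8 and otherwise move
#' to an adjacent class. Interior classes split the remaining 0.2 equally
#' between the two neighbours; edge classes fold it onto their single
#' neighbour. Jumps of more than one class never occur, so the shortest
#' lineage from `extra_small` to `extra_big` spans four generations.
#'
#' @return 5 x 5 row-stochastic matrix, rows = parent class, columns =
#'   offspring class.
#' @export
expression_transition_matrix <- function() {
  lv <- expression_levels()
  P <- matrix(0, 5, 5, dimnames = list(parent = lv, offspring = lv))
  for (i in 1:5) {
    P[i, i] <- 0.8
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= 5L]
    P[i, nb] <- 0.2 / length(nb)
  }
  P
}

#' Draw an offspring expression class
#'
#' @param parent character, parental expression class (scalar).
#' @param n number of independent draws.
#' @return character vector of offspring classes.
#' @export
offspring_expression <- function(parent, n = 1L) {
  lv <- expression_levels()
  i <- match(parent, lv)
  stopifnot(length(parent) == 1L, !is.na(i))
  P <- expression_transition_matrix()
  lv[sample.int(5L, n, replace = TRUE, prob = P[i, ])]
}

#' Draw a founder genome
#'
#' Zero-generation agents get each trait's expression class uniformly at
#' random over the five classes, then an advantage factor uniform within
#' that class's bounds; traits are independent.
#'
#' @return data.frame with one row per trait: `trait`, `expression`,
#'   `factor`, `ability`.
#' @param table trait scaling table.
#' @export
sample_genome <- function(table = default_trait_table()) {
  b <- factor_bounds()
  cls <- sample.int(5L, 6L, replace = TRUE)
  f <- stats::runif(6L, b[cls, "lo"], b[cls, "hi"])
  data.frame(
    trait = trait_names(),
    expression = expression_levels()[cls],
    factor = f,
    ability = ability_value(trait_names(), f, table),
    stringsAsFactors = FALSE
  )
}

#' Inherit a genome from a single parent
#'
#' Each gene's expression class moves through the inheritance kernel
#' independently; the offspring's advantage factor is then re-drawn
#' uniformly inside the offspring class's bounds (`policy = "redraw"`), or
#' copied verbatim when the class did not change
#' (`policy = "copy_when_same"`).
#'
#' @param parent genome data.frame as returned by [sample_genome()].
#' @param policy factor-inheritance policy.
#' @param table trait scaling table.
#' @return offspring genome data.frame.
#' @export
inherit_genome <- function(parent,
                           policy = c("redraw", "copy_when_same"),
                           table = default_trait_table()) {
  policy <- match.arg(policy)
  stopifnot(identical(parent$trait, trait_names()))
  b <- factor_bounds()
  lv <- expression_levels()
  P <- expression_transition_matrix()
  pi <- match(parent$expression, lv)
  ci <- vapply(pi, function(i) sample.int(5L, 1L, prob = P[i, ]), integer(1))
  f <- stats::runif(6L, b[ci, "lo"], b[ci, "hi"])
  if (policy == "copy_when_same") {
    same <- ci == pi
    f[same] <- parent$factor[same]
  }
  data.frame(
    trait = trait_names(),
    expression = lv[ci],
    factor = f,
    ability = ability_value(trait_names(), f, table),
    stringsAsFactors = FALSE
  )
}
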