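# The constrained normalized bivariate rational-function family used to
# couple ROM parameters to upstream mixing conditions, its 15 library
# variants, the pair/triple combination libraries and parameter counting.
#
# Two base families (X, Y are the normalized concentration and mixing time):
#   first degree : f = (p1 X Y + p4 (q2 X + q3 Y + 1)) / (q1 X Y + q2 X + q3 Y + 1)
#   second degree: f = (p1 X Y + p4 (q5 X^2 + q6 Y^2 + 1)) / (q1 X Y + q5 X^2 + q6 Y^2 + 1)
# Both satisfy f(0,0) = f(0,inf) = f(inf,0) = p4, so a blend with no
# lubricant/glidant, or one that is never mixed, behaves like the plain
# formulation regardless of the other variable.

#' Structural table of the 15 library variants
#'
#' One row per variant: base family, free shape coefficients (`free_q`),
#' whether the normalization exponents are free (`r_free`) and the count of
#' non-exponent coefficients (`n_par`).
#'
#' @return A 15-row data frame.
#' @export
variant_table <- function() {
  data.frame(
    id     = 1:15,
    family = c(rep("first", 8), "constant", rep("second", 6)),
    free_q = c("q2,q3", "q2,q3", "q2", "q2", "q3", "q3", "", "",
               "",
               "q5,q6", "q5,q6", "q5", "q5", "q6", "q6"),
    r_free = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
               FALSE,
               TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    n_par  = c(5L, 5L, 4L, 4L, 4L, 4L, 3L, 3L,
               1L,
               5L, 5L, 4L, 4L, 4L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Structural definition of a library variant
#'
#' @param id Integer variant id, 1-15. Variant 9 is the constant
#'   `f(X, Y) = p4`; variants 1-8 are first-degree forms, 10-15
#'   second-degree forms, with cross terms progressively zeroed and the
#'   normalization exponents either free or fixed at 1.
#' @return A list with `id`, `family` (`"first"`, `"second"` or
#'   `"constant"`), `free_params` (names of the free non-exponent
#'   coefficients), `r_free` and `n_par`.
#' @export
rational_variant <- function(id) {
  tab <- variant_table()
  if (!is.numeric(id) || length(id) != 1L || !(id %in% tab$id)) {
    stop("variant `id` must be an integer in 1..15")
  }
  row <- tab[tab$id == id, ]
  extra_q <- if (nzchar(row$free_q)) strsplit(row$free_q, ",")[[1]] else character()
  free <- if (row$family == "constant") "p4" else c("p1", "p4", "q1", extra_q)
  list(id = as.integer(id), family = row$family, free_params = free,
       r_free = row$r_free, n_par = row$n_par)
}

#' Normalize an upstream variable onto \[0, infinity)
#'
#' X = (v / (v_max - v))^r maps \[0, v_max) to \[0, inf): 0 at v = 0,
#' 1 at v = v_max/2 (for r = 1), diverging at the normalization cap.
#'
#' @param v Value(s) of the upstream variable (concentration in % w/w or
#'   mixing time in min); must satisfy 0 <= v < v_max.
#' @param v_max Normalization cap in the same units (2 for lubricant
#'   concentration, 0.2 for glidant, 60 min for mixing time).
#' @param r Normalization exponent in (0, 10].
#' @return The normalized value(s).
#' @export
normalize_cpp <- function(v, v_max, r = 1) {
  if (!is.finite(v_max) || v_max <= 0) stop("`v_max` must be positive")
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 10)) {
    stop("exponent `r` must be in (0, 10]")
  }
  if (any(!is.finite(v)) || any(v < 0)) stop("`v` must be finite and >= 0")
  if (any(v >= v_max - 1e-9)) {
    stop(sprintf("`v` must be below the normalization cap %g (singular at the cap)",
                 v_max))
  }
  (v / (v_max - v))^r
}

#' Normalization specification for a campaign
#'
#' Bundles the concentration and mixing-time caps used by [normalize_cpp()].
#'
#' @param c_max Concentration cap in % w/w (2 for MgSt, 0.2 for CS).
#' @param t_max Mixing-time cap in min (default 60).
#' @return A list of class `norm_spec`.
#' @export
norm_spec <- function(c_max, t_max = 60) {
  stopifnot(is.numeric(c_max), c_max > 0, is.numeric(t_max), t_max > 0)
  structure(list(c_max = c_max, t_max = t_max), class = "norm_spec")
}

# extract a coefficient from a full params vector, 0 when absent
pq <- function(params, name) {
  v <- params[[name]]
  if (is.null(v) || is.na(v)) 0 else v
}

#' Evaluate a constrained rational variant at normalized coordinates
#'
#' `X` and `Y` are the already-normalized (exponentiated) coordinates; see
#' [normalize_cpp()]. Coefficients not free in the variant are ignored
#' (treated as zero).
#'
#' @param id Variant id, 1-15.
#' @param params Named numeric vector/list with the variant's free
#'   coefficients among `p1, p4, q1, q2, q3, q5, q6`; all must be > 0
#'   (positivity is part of the family definition).
#' @param X,Y Normalized coordinates, >= 0 (vectorized).
#' @return The response value(s); equals `p4` at the origin for every
#'   variant.
#' @export
eval_rational <- function(id, params, X, Y) {
  v <- rational_variant(id)
  vals <- vapply(v$free_params, function(nm) {
    x <- params[[nm]]
    if (is.null(x) || !is.finite(x)) stop(sprintf(
      "variant %d requires parameter `%s`", v$id, nm))
    x
  }, numeric(1))
  if (any(vals <= 0)) stop("rational-function coefficients must be > 0")
  if (any(X < 0) || any(Y < 0)) stop("X and Y must be >= 0")
  eval_rational_raw(v, as.list(vals), X, Y)
}

# unchecked evaluation used inside optimization loops
eval_rational_raw <- function(v, params, X, Y) {
  p4 <- params$p4
  if (v$family == "constant") return(rep_len(p4, length(X)))
  p1 <- params$p1; q1 <- params$q1
  if (v$family == "first") {
    q2 <- pq(params, "q2"); q3 <- pq(params, "q3")
    lin <- q2 * X + q3 * Y + 1
    (p1 * X * Y + p4 * lin) / (q1 * X * Y + lin)
  } else {
    q5 <- pq(params, "q5"); q6 <- pq(params, "q6")
    sq <- q5 * X^2 + q6 * Y^2 + 1
    (p1 * X * Y + p4 * sq) / (q1 * X * Y + sq)
  }
}

#' Limiting values of a rational variant
#'
#' Returns the four corner limits of the constrained family. For every
#' variant f(0,0) = f(0,inf) = f(inf,0) = p4 (no-excipient and no-mixing
#' blends behave like the plain formulation). The joint limit is p1/q1 for
#' the first-degree family; for the second-degree family the joint limit is
#' path-dependent and the diagonal limit
#' (p1 + p4 (q5 + q6)) / (q1 + q5 + q6) is reported.
#'
#' @inheritParams eval_rational
#' @return Named numeric vector `c(f00, f0inf, finf0, finfinf)`.
#' @export
limit_values <- function(id, params) {
  v <- rational_variant(id)
  p4 <- params[["p4"]]
  if (v$family == "constant") {
    return(c(f00 = p4, f0inf = p4, finf0 = p4, finfinf = p4))
  }
  p1 <- params[["p1"]]; q1 <- params[["q1"]]
  finfinf <- if (v$family == "first") p1 / q1 else {
    q5 <- pq(params, "q5"); q6 <- pq(params, "q6")
    (p1 + p4 * (q5 + q6)) / (q1 + q5 + q6)
  }
  c(f00 = p4, f0inf = p4, finf0 = p4, finfinf = finfinf)
}

#' Pair library of variant combinations
#'
#' The 43 allowed pairs for two coupled ROM parameters: every variant pairs
#' with itself and with the constant variant 9, and variant 9 pairs with all
#' fifteen. Ordering is lexicographic.
#'
#' @return A two-column integer matrix (`id_a`, `id_b`) with 43 rows.
#' @export
pair_library <- function() {
  rows <- list()
  for (i in 1:8) rows <- c(rows, list(c(i, i), c(i, 9L)))
  for (j in 1:15) rows <- c(rows, list(c(9L, j)))
  for (i in 10:15) rows <- c(rows, list(c(i, 9L), c(i, i)))
  m <- unique(do.call(rbind, rows))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  colnames(m) <- c("id_a", "id_b")
  m
}

#' First-degree pair library
#'
#' The restriction of [pair_library()] to first-degree variants (ids 1-9):
#' the 25 combinations (i,i), (i,9) and (9,i) for i in 1..9. Used by the
#' elastic-recovery and tensile-strength stages.
#'
#' @return A two-column integer matrix with 25 rows.
#' @export
eq16_pair_library <- function() {
  m <- pair_library()
  m[m[, 1] <= 9 & m[, 2] <= 9, , drop = FALSE]
}

#' Compaction-stage triple library
#'
#' Combinations (a, 1/b, rho_c) for the compaction stage: exactly one of
#' `a` and `1/b` is held constant (variant 9) while the other and `rho_c`
#' follow a first-degree pair pattern, i.e.
#' \{(i, 9, j)\} union \{(9, i, j)\} for (i, j) in [eq16_pair_library()].
#'
#' @return A three-column integer matrix (`id_a`, `id_invb`, `id_rhoc`)
#'   with 41 rows, lexicographically ordered.
#' @export
compaction_triple_library <- function() {
  pairs <- eq16_pair_library()
  m <- rbind(
    cbind(pairs[, 1], 9L, pairs[, 2]),
    cbind(9L, pairs[, 1], pairs[, 2])
  )
  m <- unique(m)
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  colnames(m) <- c("id_a", "id_invb", "id_rhoc")
  m
}

# ---- model combinations and parameter counting --------------------------

rom_stages <- c("bulk_density", "weight", "compaction",
                "elastic_recovery", "tensile_strength")

#' Coupled parameter-function roles of a stage
#'
#' @param stage Stage name.
#' @return Character vector of role names (e.g. `c("sigma0",
#'   "rho_c_sigma")` for the tensile stage); empty for the weight stage,
#'   whose coefficients are not rational functions.
#' @export
stage_funs <- function(stage) {
  switch(stage,
    bulk_density     = "phi",
    compaction       = c("a", "inv_b", "rho_c"),
    elastic_recovery = c("eps0", "rho_c_eps"),
    tensile_strength = c("sigma0", "rho_c_sigma"),
    weight           = character()
  )
}

# response class of each coupled function: "unit" parameters live in [0,1]
fun_class <- function(fun) {
  switch(fun,
    phi = "unit", a = "unit", rho_c = "unit", eps0 = "unit",
    rho_c_eps = "unit", rho_c_sigma = "unit",
    inv_b = "positive", sigma0 = "positive",
    stop("unknown coupled function: ", fun))
}

#' Define a stage model combination
#'
#' A combination assigns one library variant to each coupled ROM parameter
#' of a stage (see [stage_funs()] roles), or, for the weight stage, picks a
#' filling-efficacy model form.
#'
#' @param stage One of `"bulk_density"`, `"weight"`, `"compaction"`,
#'   `"elastic_recovery"`, `"tensile_strength"`.
#' @param variants Named integer vector of variant ids, one per coupled
#'   parameter: `c(phi=)`, `c(a=, inv_b=, rho_c=)`, `c(eps0=, rho_c_eps=)`
#'   or `c(sigma0=, rho_c_sigma=)`. Ignored for the weight stage.
#' @param weight_form For `stage = "weight"`: `"eq21"` (legacy linear) or
#'   `"eq23"` with `zeroed` naming the xi coefficients fixed at zero.
#' @param zeroed Character vector among `c("xi1", ..., "xi5")`.
#' @return An object of class `model_combination`.
#' @examples
#' model_combination("compaction", c(a = 9, inv_b = 3, rho_c = 3))
#' model_combination("weight", weight_form = "eq23", zeroed = c("xi1", "xi5"))
#' @export
model_combination <- function(stage, variants = NULL,
                              weight_form = c("eq23", "eq21"),
                              zeroed = character()) {
  stage <- match.arg(stage, rom_stages)
  if (stage == "weight") {
    weight_form <- match.arg(weight_form)
    stopifnot(all(zeroed %in% paste0("xi", 1:5)))
    if (weight_form == "eq21") zeroed <- character()
    return(structure(list(stage = stage, variants = NULL,
                          weight_form = weight_form, zeroed = zeroed),
                     class = "model_combination"))
  }
  funs <- stage_funs(stage)
  if (is.null(variants) || !all(funs %in% names(variants))) {
    stop("`variants` must be a named vector with entries: ",
         paste(funs, collapse = ", "))
  }
  variants <- vapply(funs, function(f) as.integer(variants[[f]]), integer(1))
  for (v in variants) rational_variant(v)  # validates ids
  if (stage == "compaction" && variants[["a"]] != 9L && variants[["inv_b"]] != 9L) {
    stop("compaction combinations hold either `a` or `inv_b` constant (variant 9)")
  }
  structure(list(stage = stage, variants = variants,
                 weight_form = NULL, zeroed = NULL),
            class = "model_combination")
}

#' @export
format.model_combination <- function(x, ...) {
  if (x$stage == "weight") {
    z <- if (length(x$zeroed)) paste0(" [", paste(x$zeroed, collapse = "="),
                                      "=0]") else ""
    paste0("weight: ", x$weight_form, z)
  } else {
    paste0(x$stage, ": (", paste(x$variants, collapse = ","), ")")
  }
}

#' @export
print.model_combination <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Count the free parameters of a model combination
#'
#' Sums each member variant's free coefficients, adds the two shared
#' normalization exponents when any member has free exponents, and adds the
#' recovery exponent n for the elastic-recovery stage. For the weight stage
#' it counts the free xi coefficients of the chosen form.
#'
#' @param combination A [model_combination()], or for convenience a single
#'   variant id (counted with its own exponents, as in the library table).
#' @return Integer parameter count Np.
#' @examples
#' param_count(1)                                           # 7
#' param_count(model_combination("compaction", c(a = 9, inv_b = 3, rho_c = 3)))  # 11
#' @export
param_count <- function(combination) {
  if (is.numeric(combination) && length(combination) == 1L) {
    v <- rational_variant(combination)
    return(v$n_par + if (v$r_free) 2L else 0L)
  }
  stopifnot(inherits(combination, "model_combination"))
  if (combination$stage == "weight") {
    return(if (combination$weight_form == "eq21") 2L
           else 5L - length(combination$zeroed))
  }
  vs <- lapply(combination$variants, rational_variant)
  np <- sum(vapply(vs, `[[`, integer(1), "n_par"))
  if (any(vapply(vs, `[[`, logical(1), "r_free"))) np <- np + 2L
  if (combination$stage == "elastic_recovery") np <- np + 1L
  as.integer(np)
}

#' Default model library for a stage
#'
#' The candidate combinations ranked by [select_model()]: all 15 single
#' variants for bulk density; the five filling-efficacy forms for weight;
#' the 41 compaction triples; and the 25 first-degree pairs for elastic
#' recovery and tensile strength.
#'
#' @param stage Stage name, see [model_combination()].
#' @return A list of `model_combination` objects.
#' @export
stage_library <- function(stage) {
  stage <- match.arg(stage, rom_stages)
  if (stage == "bulk_density") {
    return(lapply(1:15, function(i) model_combination(stage, c(phi = i))))
  }
  if (stage == "weight") {
    return(list(
      model_combination("weight", weight_form = "eq21"),
      model_combination("weight", weight_form = "eq23"),
      model_combination("weight", weight_form = "eq23", zeroed = "xi1"),
      model_combination("weight", weight_form = "eq23", zeroed = "xi5"),
      model_combination("weight", weight_form = "eq23", zeroed = c("xi1", "xi5"))
    ))
  }
  if (stage == "compaction") {
    trip <- compaction_triple_library()
    return(lapply(seq_len(nrow(trip)), function(k) {
      model_combination(stage, c(a = trip[k, 1], inv_b = trip[k, 2],
                                 rho_c = trip[k, 3]))
    }))
  }
  funs <- stage_funs(stage)
  prs <- eq16_pair_library()
  lapply(seq_len(nrow(prs)), function(k) {
    v <- c(prs[k, 1], prs[k, 2]); names(v) <- funs
    model_combination(stage, v)
  })
}

#' Serialize the variant and combination libraries to JSON
#'
#' Writes the structural variant table and the pair/triple libraries for
#' audit.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library_json <- function(path) {
  obj <- list(
    variants = variant_table(),
    pair_library = as.data.frame(pair_library()),
    eq16_pair_library = as.data.frame(eq16_pair_library()),
    compaction_triple_library = as.data.frame(compaction_triple_library())
  )
  jsonlite::write_json(obj, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
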