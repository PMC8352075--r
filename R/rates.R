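#' Compile a textual rate expression
#'
#' Turns a rate expression such as `"2 + 10*x^4/(1+x^4)"` into a vectorised
#' function `f(x, t)` evaluable on arrays of states.  The expression language
#' is deliberately small: the continuum coordinates (`x` for one species, or
#' `x1`, `x2`, ... in general), time `t`, declared parameter names, the
#' arithmetic operators `+ - * / ^` and parentheses, comparisons (for use in
#' `indicator`), and the functions `exp`, `log`, `sqrt`, `abs`, `pow`, `min`,
#' `max` (elementwise), `hill(x, r0, r1, n)` and `indicator(condition)`.
#' Compilation is deterministic and purely syntactic; any other symbol is a
#' compile error naming the offender.
#'
#' @param expr character scalar, the rate expression.
#' @param params named list/vector of numeric parameters referenced by name.
#' @param d number of continuum species (dimension); coordinates are `x`
#'   (alias of `x1`) and `x1`..`xd`.
#' @return a function `f(x, t)`; `x` is a numeric vector (`d = 1`) or a
#'   matrix with `d` columns.  The source text is kept in `attr(, "expr")`.
#' @examples
#' f <- rate_expression_compile("2 + 10*x^4/(1+x^4)")
#' f(0)           # 2
#' g <- rate_expression_compile("L*x*(1-x)", params = list(L = 3))
#' g(0.5)         # 0.75
#' @export
rate_expression_compile <- function(expr, params = list(), d = 1L) {
  stopifnot(is.character(expr), length(expr) == 1L)
  d <- as.integer(d)
  coord_names <- c("x", paste0("x", seq_len(d)))
  allowed_syms <- c(coord_names, "t", names(params))
  allowed_calls <- c("+", "-", "*", "/", "^", "(",
                     "<", "<=", ">", ">=", "==", "!=", "&", "|", "!",
                     "exp", "log", "sqrt", "abs", "pow", "min", "max",
                     "hill", "indicator")
  ast <- tryCatch(str2lang(expr),
                  error = function(e) stop("cannot parse rate expression: ",
                                           conditionMessage(e), call. = FALSE))
  walk <- function(node) {
    if (is.symbol(node)) {
      s <- as.character(node)
      if (!s %in% allowed_syms)
        stop("unknown symbol '", s, "' in rate expression", call. = FALSE)
      return(invisible())
    }
    if (is.atomic(node)) {
      if (!is.numeric(node) && !is.logical(node))
        stop("only numeric literals are allowed in rate expressions",
             call. = FALSE)
      return(invisible())
    }
    if (is.call(node)) {
      head <- node[[1]]
      if (!is.symbol(head) || !as.character(head) %in% allowed_calls)
        stop("unknown symbol '", deparse(head), "' in rate expression",
             call. = FALSE)
      for (i in seq_along(node)[-1]) walk(node[[i]])
      return(invisible())
    }
    stop("unsupported construct in rate expression", call. = FALSE)
  }
  walk(ast)

  base_env <- new.env(parent = baseenv())
  for (nm in names(params)) assign(nm, as.numeric(params[[nm]]), envir = base_env)
  assign("min", base::pmin, envir = base_env)
  assign("max", base::pmax, envir = base_env)
  assign("pow", function(a, b) a^b, envir = base_env)
  assign("hill", hill_rate, envir = base_env)
  assign("indicator", function(cond) as.numeric(cond), envir = base_env)

  f <- function(x, t = 0) {
    e <- new.env(parent = base_env)
    if (is.matrix(x)) {
      for (j in seq_len(ncol(x))) assign(paste0("x", j), x[, j], envir = e)
      assign("x", x[, 1], envir = e)
    } else {
      assign("x", x, envir = e)
      assign("x1", x, envir = e)
    }
    assign("t", t, envir = e)
    v <- eval(ast, e)
    if (length(v) == 1L) v <- rep.int(as.numeric(v), NROW(x))
    v
  }
  attr(f, "expr") <- expr
  attr(f, "params") <- params
  f
}
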