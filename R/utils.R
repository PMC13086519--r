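`%||%` <- function(a, b) if (is.null(a)) b else a

# merge a user-supplied (possibly partial) named vector into defaults
.merge_named <- function(default, user, what = "parameter") {
  if (is.null(user)) return(default)
  if (is.null(names(user)) || any(names(user) == "")) {
    stop("all ", what, " values must be named", call. = FALSE)
  }
  bad <- setdiff(names(user), names(default))
  if (length(bad)) {
    stop("unknown ", what, " name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  default[names(user)] <- user
  default
}

# trapezoidal integral; x must be sorted
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# YAML 1.1 parses the bare scalar NO as boolean false; recover the gas
# species symbol while leaving genuine booleans alone
.yaml_handlers <- list(
  "bool#no" = function(x) if (identical(x, "NO")) "NO" else FALSE,
  "bool#yes" = function(x) TRUE)

.read_yaml <- function(path) yaml::read_yaml(path, handlers = .yaml_handlers)
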