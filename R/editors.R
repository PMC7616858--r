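#' Base-editor specification
#'
#' Describes a base editor by its conversion chemistry, editing window and
#' PAM requirement. The adenine base editor (ABE) converts A to G and the
#' cytosine base editor (CBE) converts C to T, both on the protospacer
#' strand. The window is given in protospacer positions counted 1..20 from
#' the PAM-distal 5' end; positions 4-8 are the conventional high-activity
#' window for the NGN-PAM editors modelled here, and results depend on it,
#' so it is exposed rather than hard-coded.
#'
#' @param name `"ABE"` or `"CBE"`.
#' @param window Integer length-2: inclusive protospacer window (default
#'   `c(4, 8)`).
#' @param pam IUPAC PAM pattern, 3 nt (default `"NGN"`).
#' @return An object of class `editor_spec`.
#' @examples
#' editor_spec("ABE")
#' editor_spec("CBE", window = c(3, 9))
#' @export
editor_spec <- function(name = c("ABE", "CBE"), window = c(4L, 8L),
                        pam = "NGN") {
  name <- arg_match(name)
  window <- as.integer(window)
  if (length(window) != 2 || is.na(window[1]) || is.na(window[2]) ||
      window[1] < 1 || window[2] > 20 || window[1] > window[2]) {
    abort("window must satisfy 1 <= start <= end <= 20")
  }
  if (nchar(pam) != 3) abort("PAM pattern must be 3 nt")
  conv <- switch(name, ABE = c(from = "A", to = "G"),
                 CBE = c(from = "C", to = "T"))
  structure(
    list(name = name, from = unname(conv["from"]), to = unname(conv["to"]),
         window = window, pam = toupper(pam)),
    class = "editor_spec"
  )
}

#' @export
print.editor_spec <- function(x, ...) {
  cat(sprintf("<editor_spec> %s: %s->%s, window %d-%d, PAM %s\n",
              x$name, x$from, x$to, x$window[1], x$window[2], x$pam))
  invisible(x)
}

as_editor_spec <- function(editor) {
  if (inherits(editor, "editor_spec")) return(editor)
  if (is.character(editor) && length(editor) == 1) return(editor_spec(editor))
  abort("editor must be an editor_spec or \"ABE\"/\"CBE\"")
}
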