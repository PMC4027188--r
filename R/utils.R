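`%||%` <- function(x, y) if (is.null(x)) y else x

# Dense matrix exponential (small generators only).
.expm <- function(M) {
  as.matrix(Matrix::expm(Matrix::Matrix(M, sparse = FALSE)))
}
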