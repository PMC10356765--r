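// AVX2+FMA instantiation of the convolution kernels; compiled with
// -mavx2 -mfma (see Makevars) and selected at run time only on CPUs that
// report both features.
#define SINUSPLAN_KERNEL_NS sinusplan_avx2
#include "conv_kernels.h"
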