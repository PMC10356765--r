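// Baseline (portable) instantiation of the convolution kernels.
#define SINUSPLAN_KERNEL_NS sinusplan_base
#include "conv_kernels.h"
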