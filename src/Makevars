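PKG_CXXFLAGS = -funroll-loops

all: $(SHLIB)

# The AVX2 kernel build appends its ISA flags after the system CXXFLAGS so
# they take effect; the resulting object is only executed on CPUs that
# report avx2+fma (runtime dispatch in tensor_ops.cpp).
kernels_avx2.o: kernels_avx2.cpp conv_kernels.h
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) $(CXXPICFLAGS) -O3 -mavx2 -mfma -funroll-loops -c kernels_avx2.cpp -o kernels_avx2.o
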