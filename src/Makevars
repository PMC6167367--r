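# The permutation null requires ~10^5 bilateral filter passes per study; the
# hot loops are written branch-free and dependence-free so gcc can vectorise
# exp() through libmvec.  That needs the full -ffast-math set plus the widest
# vector unit of the build host.  The toolchain's Makeconf appends its own
# CXXFLAGS (with a conservative -march baseline) after PKG_CXXFLAGS, so a
# pattern rule is used to append these last, where they take precedence.
EXTRA_OPT = -O3 -ffast-math -march=native

%.o: %.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) $(EXTRA_OPT) -c $< -o $@
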