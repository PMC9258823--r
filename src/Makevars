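# The bundled conda toolchain targets a sysroot glibc newer than the runtime
# loader's, so shared objects it builds cannot be dlopen'ed into R; build
# with the system compiler against the runtime glibc instead.
override CC = gcc
override CXX = g++
override CXX17 = g++
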